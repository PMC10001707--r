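# Plot helpers for scenario grids and annual plans.

#' Plot a scenario grid
#'
#' Stabilized monthly means against total inflow, one line per
#' reclaimed-water fraction, faceted by month.
#'
#' @param grid A [scenario_grid()] result.
#' @param var `"mean_sd"` (cm) or `"mean_chl"` (µg/L).
#' @return A ggplot object.
#' @export
plot_scenario_grid <- function(grid, var = c("mean_sd", "mean_chl")) {
  var <- match.arg(var)
  ylab <- if (var == "mean_sd") "stabilized mean SD (cm)" else
    "stabilized mean Chl-a (µg/L)"
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$q_total, y = .data[[var]],
                                     colour = factor(.data$rw_fraction))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~month, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "total inflow (m³/s)", y = ylab,
                  colour = "RW fraction") +
    ggplot2::theme_bw()
}

#' Plot an annual replenishment plan
#'
#' Monthly minimum flows of the optimized plan and the single-source
#' baselines.
#'
#' @param plan An [annual_plan()] result.
#' @return A ggplot object.
#' @export
plot_annual_plan <- function(plan) {
  s <- plan$schedule
  long <- dplyr::bind_rows(
    tibble::tibble(month = s$month, scheme = "optimized", q = s$q_min),
    tibble::tibble(month = s$month, scheme = "SW only", q = s$q_sw),
    tibble::tibble(month = s$month, scheme = "RW only", q = s$q_rw)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$month), y = .data$q,
                                     fill = .data$scheme)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "month", y = "minimum total inflow (m³/s)",
                  fill = NULL) +
    ggplot2::theme_bw()
}
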