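# Model skill metrics and parameter calibration against observation series.

#' Root mean square error
#'
#' @param observed,simulated Numeric vectors of equal, non-zero length.
#' @return `sqrt(mean((observed - simulated)^2))`, in the units of the
#'   compared variable.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 4)) # sqrt(1/3)
#' @export
rmse <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    stop("observed and simulated must have equal length")
  }
  if (!length(observed)) stop("empty input")
  if (any(!is.finite(observed)) || any(!is.finite(simulated))) {
    stop("inputs must be finite")
  }
  sqrt(mean((observed - simulated)^2))
}

#' Nash-Sutcliffe efficiency
#'
#' `1 - SSE / SST`; 1 for a perfect match, 0 for a model no better than the
#' observed mean, negative below that. Undefined (rejected) when the observed
#' series has zero variance.
#'
#' @param observed,simulated Numeric vectors of equal length, at least 2.
#' @return The efficiency, a dimensionless value `<= 1`.
#' @examples
#' nse(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
nse <- function(observed, simulated) {
  if (length(observed) != length(simulated)) {
    stop("observed and simulated must have equal length")
  }
  if (length(observed) < 2) stop("NSE needs at least 2 paired points")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    stop("NSE is undefined: the observed series has zero variance")
  }
  1 - sum((observed - simulated)^2) / sst
}

#' Chronological calibration/validation split
#'
#' Splits a monthly observation table at a month boundary: calibration months
#' `1..split_month`, validation months `split_month+1..12`.
#'
#' @param observations A tibble with a `month` column (1-12).
#' @param split_month Last calibration month (default 7, a January-July /
#'   August-December split).
#' @return A list with elements `calibration` and `validation`.
#' @export
split_calibration_validation <- function(observations, split_month = 7) {
  if (!"month" %in% names(observations)) {
    stop("observations must have a month column")
  }
  if (split_month < 1 || split_month > 12) stop("split_month must lie in 1-12")
  list(calibration = observations[observations$month <= split_month, ],
       validation = observations[observations$month > split_month, ])
}

# Build a fast predictor closure for the historical-mode year: the forcing
# arrays and the mid-month sampling indices (day 15, 10:00, once a month) are
# prepared once; each call then only runs the compiled core with a new
# parameter set and extracts the sampled state.
make_monthly_predictor <- function(forcing, q_total,
                                   coeffs = optical_coefficients(),
                                   geometry = lake_geometry(),
                                   loads = external_loads(),
                                   iss_fraction = 0.75, dt = 1800) {
  arr <- prepare_sim_arrays(forcing, influent_schedule(iss_fraction),
                            q_total, loads, dt, dt)
  mday <- as.integer(strftime(forcing$time, "%d", tz = "UTC"))
  hour <- as.integer(strftime(forcing$time, "%H", tz = "UTC"))
  months_present <- sort(unique(arr$month))
  idx <- vapply(months_present, function(mo) {
    cand <- which(arr$month == mo & mday == 15 & hour == 10)
    if (!length(cand)) cand <- which(arr$month == mo)
    cand[1]
  }, integer(1))
  sample_time <- forcing$time[idx]
  dt_days <- dt / SECONDS_PER_DAY
  opt_vec <- pack_optics(coeffs)

  function(params) {
    init <- lake_state(chl = 5, dc = 1, iss = 10, nh4 = 0.5, no3 = 1.5,
                       ip = 0.05, chl_to_c = params$chl_to_c)
    res <- sim_core(state_vector(init), dt_days, arr$t_water, arr$i_surface,
                    arr$inflow_mat, arr$q_in_m3d, arr$q_runoff,
                    arr$runoff_conc, arr$dep, pack_params(params), opt_vec,
                    geometry$volume, geometry$depth)
    s <- res$states[idx, , drop = FALSE]
    chl <- params$chl_to_c * s[, 1]
    budget <- optical_budget(list(chl = chl, iss = s[, 3], dc = s[, 2]),
                             coeffs)
    tibble::tibble(
      month = months_present,
      time = sample_time,
      sd_cm = budget$sd * 100,
      chl = chl,
      iss = s[, 3],
      nh4 = s[, 4],
      no3 = s[, 5],
      ip = s[, 6]
    )
  }
}

#' Calibrate kinetic parameters against observations
#'
#' Minimizes the summed mean-normalized RMSE across the observed variables by
#' a seeded derivative-free local search (Nelder-Mead in log-parameter space)
#' started from Latin-hypercube multistarts plus the supplied start point.
#' Normalizing each variable's RMSE by its observed mean makes mg/L and µg/L
#' variables weigh comparably. The returned objective is never worse than the
#' objective at the start point. Deterministic given `seed`.
#'
#' @param observations Tibble of monthly observations with a `month` column
#'   and any of `sd_cm`, `chl`, `iss`, `nh4`, `no3`, `ip`.
#' @param forcing The forcing series the observations were collected under.
#' @param free Names of the [eco_params()] fields to calibrate.
#' @param start Optional named start vector; defaults to the values in
#'   `params`.
#' @param lower,upper Named bounds; default to 0.2x and 5x the start.
#' @param params Fixed values of the non-free parameters.
#' @param coeffs,geometry,loads,iss_fraction,q_total,dt Simulation
#'   configuration (must mirror how the observations were generated or
#'   collected).
#' @param variables Observed variables used in the objective; defaults to all
#'   recognized columns present.
#' @param seed Integer seed for the multistart design.
#' @param n_starts Number of Latin-hypercube starts in addition to `start`.
#' @param maxit Nelder-Mead iteration budget per start.
#' @return A list of class `calibration_result`: `params` (full
#'   [eco_params()] with fitted values), `fitted` (named vector),
#'   `objective`, `start_objective`, `skill` (tibble of per-variable RMSE and
#'   NSE), `n_evaluations`, and `seed`.
#' @export
calibrate <- function(observations, forcing,
                      free = c("mypc", "deac", "chl_to_c"),
                      start = NULL, lower = NULL, upper = NULL,
                      params = eco_params(),
                      coeffs = optical_coefficients(),
                      geometry = lake_geometry(),
                      loads = external_loads(),
                      iss_fraction = 0.75, q_total = 0.1, dt = 1800,
                      variables = NULL, seed = 1, n_starts = 3,
                      maxit = 200) {
  known <- c("sd_cm", "chl", "iss", "nh4", "no3", "ip")
  if (is.null(variables)) variables <- intersect(known, names(observations))
  if (!length(variables)) stop("observations carry none of the recognized variables")
  if (!all(free %in% names(params))) {
    stop("unknown free parameters: ",
         paste(setdiff(free, names(params)), collapse = ", "))
  }
  if (is.null(start)) start <- unlist(params[free])
  start <- start[free]
  if (any(start <= 0)) stop("start values must be positive (log-space search)")
  if (is.null(lower)) lower <- start * 0.2
  if (is.null(upper)) upper <- start * 5
  lower <- lower[free]; upper <- upper[free]

  predictor <- make_monthly_predictor(forcing, q_total, coeffs, geometry,
                                      loads, iss_fraction, dt)
  obs_means <- vapply(variables, function(v) mean(observations[[v]]), numeric(1))
  if (any(obs_means <= 0)) stop("observed means must be positive for normalization")

  n_eval <- 0L
  objective_for <- function(theta) {
    # theta on log scale
    vals <- exp(theta)
    if (any(vals < lower) || any(vals > upper)) return(1e6)
    p <- params
    p[free] <- as.list(vals)
    pred <- tryCatch(predictor(p), error = function(e) NULL)
    n_eval <<- n_eval + 1L
    if (is.null(pred)) return(1e6)
    pred <- pred[match(observations$month, pred$month), ]
    sum(vapply(variables, function(v) {
      rmse(observations[[v]], pred[[v]]) / obs_means[[v]]
    }, numeric(1)))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  k <- length(free)
  starts <- list(log(start))
  if (n_starts > 0) {
    u <- lhs::randomLHS(n_starts, k)
    for (i in seq_len(n_starts)) {
      starts[[i + 1]] <- log(lower) + u[i, ] * (log(upper) - log(lower))
    }
  }

  start_objective <- objective_for(log(start))
  best_val <- start_objective
  best_theta <- log(start)
  if (start_objective > 1e-12) {
    for (th0 in starts) {
      fit <- optim(th0, objective_for, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-8))
      if (fit$value < best_val) {
        best_val <- fit$value
        best_theta <- fit$par
      }
    }
  }
  if (!is.finite(best_val) || best_val >= 1e6) {
    stop("objective was non-finite or degenerate at every start point")
  }

  fitted <- setNames(exp(best_theta), free)
  p_fit <- params
  p_fit[free] <- as.list(fitted)
  pred <- predictor(p_fit)
  pred <- pred[match(observations$month, pred$month), ]
  skill <- tibble::tibble(
    variable = variables,
    rmse = vapply(variables, function(v) rmse(observations[[v]], pred[[v]]),
                  numeric(1)),
    nse = vapply(variables, function(v) {
      tryCatch(nse(observations[[v]], pred[[v]]), error = function(e) NA_real_)
    }, numeric(1))
  )
  structure(
    list(params = p_fit, fitted = fitted, objective = best_val,
         start_objective = start_objective, skill = skill,
         n_evaluations = n_eval, seed = seed),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration result (objective ", format(x$objective, digits = 5),
      ", started at ", format(x$start_objective, digits = 5), ")\n", sep = "")
  print(round(x$fitted, 5))
  print(x$skill)
  invisible(x)
}

#' Model skill of a parameter set on held-out observations
#'
#' Convenience wrapper: simulates with `params` under `forcing` and reports
#' per-variable RMSE and NSE against `observations`.
#'
#' @inheritParams calibrate
#' @param params The parameter set to evaluate.
#' @return A tibble with columns `variable`, `rmse`, `nse`.
#' @export
skill_report <- function(observations, forcing, params,
                         coeffs = optical_coefficients(),
                         geometry = lake_geometry(),
                         loads = external_loads(),
                         iss_fraction = 0.75, q_total = 0.1, dt = 1800,
                         variables = NULL) {
  known <- c("sd_cm", "chl", "iss", "nh4", "no3", "ip")
  if (is.null(variables)) variables <- intersect(known, names(observations))
  pred <- simulate_observation_truth(params, coeffs, forcing, q_total,
                                     geometry, loads, iss_fraction, dt)
  pred <- pred[match(observations$month, pred$month), ]
  tibble::tibble(
    variable = variables,
    rmse = vapply(variables, function(v) rmse(observations[[v]], pred[[v]]),
                  numeric(1)),
    nse = vapply(variables, function(v) {
      tryCatch(nse(observations[[v]], pred[[v]]), error = function(e) NA_real_)
    }, numeric(1))
  )
}
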