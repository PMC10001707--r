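# Time integration of the box model.

#' Simulate the lake through time
#'
#' Advances the well-mixed lake state with an explicit Euler scheme at the
#' forcing time step (at most 30 min) and returns the trajectory at the
#' output cadence (default 90 min) together with the optical budget and
#' Secchi depth at every output instant. Deterministic given its inputs.
#'
#' @param initial A [lake_state()].
#' @param forcing Tibble with columns `time` (POSIXct, uniform step `dt`),
#'   `t_water`, `i_surface` and `rainfall` covering the whole run; a gap or
#'   irregular step is rejected naming the offending interval.
#' @param inflow Either a single inflow (a [blend_sources()] result or list
#'   with `nh4`, `no3`, `ip`, `iss`, `dc_in`) applied throughout, or a
#'   12-row monthly schedule (tibble with a `month` column and the same
#'   constituent columns) matched to each time step's calendar month.
#' @param q_total Total replenishment inflow (m³/s), scalar or one value per
#'   forcing step.
#' @param params,coeffs,geometry Model parameter objects.
#' @param loads An [external_loads()] spec; dry deposition is taken from its
#'   monthly table by calendar month and runoff from the forcing rainfall.
#'   Use `NULL` to disable both.
#' @param dt Integration step (s); must equal the forcing step and be at most
#'   1800.
#' @param output_dt Output cadence (s); must be a multiple of `dt`. Default
#'   5400 (90 min).
#' @param engine `"cpp"` (compiled core, default) or `"r"` (reference R loop;
#'   slow, intended for verification).
#' @return A tibble with columns `time`, `pc`, `dc`, `iss`, `nh4`, `no3`,
#'   `ip`, `chl`, `a`, `b`, `c`, `kd`, `sd` (m). The number of rows is
#'   `duration / output_dt + 1`. Attribute `clipped` counts non-negativity
#'   clips during integration.
#' @examples
#' f <- month_climatology(4, days = 2)
#' inflow <- blend_sources(p = 0.5)
#' sim <- simulate_lake(lake_state(chl = 5, iss = 20), f, inflow, q_total = 0.2)
#' tail(sim[, c("time", "chl", "sd")], 3)
#' @export
simulate_lake <- function(initial, forcing, inflow, q_total,
                          params = eco_params(),
                          coeffs = optical_coefficients(),
                          geometry = lake_geometry(),
                          loads = external_loads(),
                          dt = 1800, output_dt = 5400,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!inherits(initial, "lake_state")) stop("initial must be a lake_state")
  arr <- prepare_sim_arrays(forcing, inflow, q_total, loads, dt, output_dt)
  n <- arr$n

  y0 <- state_vector(initial)
  dt_days <- dt / SECONDS_PER_DAY

  if (engine == "cpp") {
    res <- sim_core(y0, dt_days, arr$t_water, arr$i_surface,
                    arr$inflow_mat, arr$q_in_m3d, arr$q_runoff,
                    arr$runoff_conc, arr$dep, pack_params(params),
                    pack_optics(coeffs), geometry$volume, geometry$depth)
    states <- res$states
    clipped <- res$clipped
  } else {
    inflow_mat <- arr$inflow_mat
    dep <- arr$dep
    q_runoff <- arr$q_runoff
    runoff_conc <- setNames(arr$runoff_conc, c("nh4", "no3", "ip"))
    q_in_m3d <- arr$q_in_m3d
    states <- matrix(NA_real_, n + 1, 6)
    states[1, ] <- y0
    clipped <- 0
    st <- initial
    for (i in seq_len(n)) {
      st <- lake_step(st, dt = dt,
                      t_water = forcing$t_water[i],
                      i_surface = forcing$i_surface[i],
                      inflow = list(nh4 = inflow_mat[i, 1], no3 = inflow_mat[i, 2],
                                    ip = inflow_mat[i, 3], iss = inflow_mat[i, 4],
                                    dc_in = inflow_mat[i, 5]),
                      q_total = q_in_m3d[i] / SECONDS_PER_DAY,
                      params = params, coeffs = coeffs, geometry = geometry,
                      deposition = c(nh4 = unname(dep[i, 1]),
                                     no3 = unname(dep[i, 2]),
                                     ip = unname(dep[i, 3])),
                      q_runoff = q_runoff[i], runoff_conc = runoff_conc)
      clipped <- clipped + attr(st, "clipped")
      states[i + 1, ] <- state_vector(st)
    }
  }

  every <- output_dt %/% dt
  keep <- seq(1, n + 1, by = every)
  out_time <- c(forcing$time, forcing$time[n] + dt)[keep]
  s <- states[keep, , drop = FALSE]
  chl <- params$chl_to_c * s[, 1]
  budget <- optical_budget(list(chl = chl, iss = s[, 3], dc = s[, 2]), coeffs)
  out <- tibble::tibble(
    time = out_time,
    pc = s[, 1], dc = s[, 2], iss = s[, 3],
    nh4 = s[, 4], no3 = s[, 5], ip = s[, 6],
    chl = chl,
    a = budget$a, b = budget$b, c = budget$c, kd = budget$kd, sd = budget$sd
  )
  attr(out, "clipped") <- clipped
  out
}

# Validate a forcing series and assemble the per-step arrays the compiled
# core consumes. Factored out of simulate_lake() so repeated evaluations of
# the same forcing (calibration objectives) can prepare the arrays once.
prepare_sim_arrays <- function(forcing, inflow, q_total, loads,
                               dt = 1800, output_dt = 5400) {
  need <- c("time", "t_water", "i_surface", "rainfall")
  missing_cols <- setdiff(need, names(forcing))
  if (length(missing_cols)) {
    stop("forcing is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(forcing)
  if (n < 2) stop("forcing must contain at least two steps")
  steps <- diff(as.numeric(forcing$time))
  if (any(abs(steps - dt) > 1e-6)) {
    bad <- which(abs(steps - dt) > 1e-6)[1]
    stop("forcing has a gap or irregular step between ",
         format(forcing$time[bad]), " and ", format(forcing$time[bad + 1]),
         " (expected dt = ", dt, " s)")
  }
  if (dt > 1800) stop("dt must be at most 1800 s")
  if (output_dt %% dt != 0) stop("output_dt must be a multiple of dt")

  # a `month` column on the forcing (as produced by month_climatology())
  # pins the calendar month of monthly inflow schedules and deposition loads,
  # so stationary single-month scenarios can run for arbitrary durations
  month <- if ("month" %in% names(forcing)) {
    as.integer(forcing$month)
  } else {
    as.integer(strftime(forcing$time, "%m", tz = "UTC"))
  }

  # per-step inflow concentration matrix (nh4, no3, ip, iss, dc_in)
  if (is.data.frame(inflow)) {
    if (!all(c("month", "nh4", "no3", "ip", "iss", "dc_in") %in% names(inflow))) {
      stop("a monthly inflow schedule needs columns month, nh4, no3, ip, iss, dc_in")
    }
    sched <- inflow[match(month, inflow$month), ]
    if (any(is.na(sched$nh4))) {
      stop("inflow schedule does not cover every month in the run")
    }
    inflow_mat <- cbind(sched$nh4, sched$no3, sched$ip, sched$iss, sched$dc_in)
  } else {
    inflow_mat <- matrix(c(inflow$nh4, inflow$no3, inflow$ip, inflow$iss,
                           inflow$dc_in),
                         nrow = n, ncol = 5, byrow = TRUE)
  }

  if (is.null(loads)) {
    dep <- matrix(0, n, 3)
    q_runoff <- numeric(n)
    runoff_conc <- c(0, 0, 0)
  } else {
    dep_tab <- t(vapply(1:12, deposition_flux, numeric(3)))
    dep <- dep_tab[month, , drop = FALSE]
    dt_days <- dt / SECONDS_PER_DAY
    q_runoff <- runoff_load(forcing$rainfall, loads)$volume / dt_days # m3/day
    runoff_conc <- unname(loads$runoff_conc)
  }

  list(n = n, t_water = forcing$t_water, i_surface = forcing$i_surface,
       inflow_mat = inflow_mat, q_in_m3d = rep_len(q_total, n) * SECONDS_PER_DAY,
       q_runoff = q_runoff, runoff_conc = runoff_conc, dep = dep,
       month = month, time = forcing$time)
}
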