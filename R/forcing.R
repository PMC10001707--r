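# Synthetic forcing and external nutrient sources.
#
# The package carries no measured meteorology; it synthesizes water
# temperature, solar irradiance and rainfall for a temperate continental site
# (defaults approximate Xi'an, 34.3 degN: coldest water ~4 degC in late
# January, warmest ~28 degC in late July, summer-peaking rainfall). All
# generators are pure functions of (config, seed).

#' Forcing generator configuration
#'
#' @param t_mean Annual mean water temperature (degC).
#' @param t_amp Seasonal half-amplitude of water temperature (degC).
#' @param t_peak_doy Day of year of the water-temperature maximum.
#' @param t_noise_sd Standard deviation of the daily AR(1) temperature noise
#'   (degC); used only by the stochastic generator.
#' @param latitude Site latitude (degrees N), drives day length and solar
#'   elevation.
#' @param solar_constant Top-of-atmosphere normal irradiance (W/m²).
#' @param atm_transmission Clear-sky atmospheric transmission factor.
#' @param cloud_mean Mean daily cloudiness transmission factor (0-1 scale,
#'   1 = clear).
#' @param cloud_sd Standard deviation of the daily cloudiness factor.
#' @param rain_monthly Monthly rainfall normals (mm), January-December.
#' @param rain_events Expected number of rain events per month.
#' @return A list of class `forcing_config`.
#' @export
forcing_config <- function(t_mean = 16, t_amp = 12, t_peak_doy = 207.5,
                           t_noise_sd = 0.8,
                           latitude = 34.3, solar_constant = 1100,
                           atm_transmission = 0.70,
                           cloud_mean = 0.72, cloud_sd = 0.15,
                           rain_monthly = c(7, 10, 22, 40, 54, 60,
                                            99, 75, 92, 60, 24, 6),
                           rain_events = c(3, 4, 6, 8, 9, 9,
                                           10, 9, 10, 8, 5, 3)) {
  if (length(rain_monthly) != 12 || any(rain_monthly < 0)) {
    stop("rain_monthly must be 12 non-negative monthly totals")
  }
  if (cloud_mean <= 0 || cloud_mean > 1) stop("cloud_mean must lie in (0, 1]")
  structure(
    list(t_mean = t_mean, t_amp = t_amp, t_peak_doy = t_peak_doy,
         t_noise_sd = t_noise_sd, latitude = latitude,
         solar_constant = solar_constant, atm_transmission = atm_transmission,
         cloud_mean = cloud_mean, cloud_sd = cloud_sd,
         rain_monthly = rain_monthly, rain_events = rain_events),
    class = "forcing_config"
  )
}

# Seasonal water-temperature climatology (degC) as a function of day of year.
water_temperature_climatology <- function(doy, config = forcing_config()) {
  t <- config$t_mean +
    config$t_amp * cos(2 * pi * (doy - config$t_peak_doy) / 365.25)
  pmin(pmax(t, 0), 35)
}

# Clear-sky irradiance (W/m2) from solar geometry at fractional day of year
# `doy` (doy 1.5 = noon Jan 1) and hour-of-day `hour`.
clear_sky_irradiance <- function(doy, hour, config = forcing_config()) {
  decl <- 23.44 * pi / 180 * sin(2 * pi * (doy - 81) / 365.25)
  lat <- config$latitude * pi / 180
  hour_angle <- pi * (hour - 12) / 12
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(hour_angle)
  config$solar_constant * config$atm_transmission * pmax(cosz, 0)
}

#' Synthesize a meteorological forcing series
#'
#' Generates water temperature (seasonal sinusoid plus optional daily AR(1)
#' noise, clipped to \[0, 35\] degC), surface irradiance (clear-sky solar
#' geometry times a stochastic daily cloudiness factor; zero at night) and
#' rainfall (a seeded marked point process whose event depths are rescaled so
#' each month matches its configured total exactly). The result is a uniform
#' series with one row per time step; it is a pure function of
#' `(config, seed)`.
#'
#' @param days Length of the series in days.
#' @param dt Time step in seconds (at most 1800).
#' @param start Start time (POSIXct, UTC); defaults to midnight January 1.
#' @param seed Integer seed; same seed, same series.
#' @param config A [forcing_config()].
#' @param climatology If `TRUE`, suppress all stochastic components: mean
#'   cloudiness, no temperature noise, and monthly rainfall spread uniformly
#'   over each month. The result is then deterministic and `seed` is unused.
#' @return A tibble with columns `time`, `t_water` (degC), `i_surface`
#'   (W/m²) and `rainfall` (mm per step).
#' @examples
#' f <- synth_forcing(days = 2, seed = 1)
#' range(f$t_water)
#' @export
synth_forcing <- function(days = 365, dt = 1800,
                          start = as.POSIXct("2021-01-01", tz = "UTC"),
                          seed = 1, config = forcing_config(),
                          climatology = FALSE) {
  if (dt <= 0 || dt > 1800) stop("dt must be positive and at most 1800 s")
  n <- round(days * SECONDS_PER_DAY / dt)
  time <- start + dt * (seq_len(n) - 1)
  start_doy <- as.numeric(strftime(start, "%j", tz = "UTC"))
  frac_day <- (as.numeric(time) - as.numeric(start)) / SECONDS_PER_DAY
  doy <- (start_doy - 1 + frac_day) %% 365.25 + 0.5 * dt / SECONDS_PER_DAY
  hour <- (as.numeric(time) %% SECONDS_PER_DAY) / 3600 +
    0.5 * dt / 3600
  month <- as.integer(strftime(time, "%m", tz = "UTC"))
  day_index <- floor(frac_day) + 1
  n_days <- max(day_index)

  t_clim <- water_temperature_climatology(doy, config)
  i_clear <- clear_sky_irradiance(doy, hour, config)

  if (climatology) {
    t_water <- t_clim
    i_surface <- i_clear * config$cloud_mean
    steps_in_month <- tabulate(month, nbins = 12)
    rainfall <- config$rain_monthly[month] / steps_in_month[month]
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)

    ar <- numeric(n_days)
    innov <- rnorm(n_days, sd = config$t_noise_sd * sqrt(1 - 0.8^2))
    for (i in seq_len(n_days)) {
      ar[i] <- if (i == 1) rnorm(1, sd = config$t_noise_sd) else
        0.8 * ar[i - 1] + innov[i]
    }
    t_water <- pmin(pmax(t_clim + ar[day_index], 0), 35)

    m <- config$cloud_mean
    v <- min(config$cloud_sd, sqrt(m * (1 - m)) * 0.95)^2
    shape_sum <- m * (1 - m) / v - 1
    cloud_day <- rbeta(n_days, shape1 = m * shape_sum,
                       shape2 = (1 - m) * shape_sum)
    i_surface <- i_clear * cloud_day[day_index]

    # marked point process: each event starts at a random step and spreads
    # its depth over a sampled duration (0.5-12 h); depths are rescaled so
    # every month matches its configured total exactly
    rainfall <- numeric(n)
    steps_per_hour <- 3600 / dt
    for (mo in sort(unique(month))) {
      idx <- which(month == mo)
      total <- config$rain_monthly[mo]
      if (total <= 0) next
      n_events <- max(1L, rpois(1, config$rain_events[mo]))
      at <- sample(idx, n_events, replace = TRUE)
      depth <- rgamma(n_events, shape = 1.2, rate = 1)
      depth <- depth * total / sum(depth)
      dur <- pmax(1L, round(rgamma(n_events, shape = 2, scale = 2) *
                              steps_per_hour))
      for (j in seq_len(n_events)) {
        span <- at[j]:min(at[j] + dur[j] - 1L, n)
        rainfall[span] <- rainfall[span] + depth[j] / length(span)
      }
    }
    # depth falling past the series end stays in the month via the rescale
    for (mo in sort(unique(month))) {
      idx <- which(month == mo)
      tot <- sum(rainfall[idx])
      if (tot > 0) {
        rainfall[idx] <- rainfall[idx] * config$rain_monthly[mo] / tot
      }
    }
  }

  tibble::tibble(time = time, t_water = as.numeric(t_water),
                 i_surface = as.numeric(i_surface),
                 rainfall = as.numeric(rainfall))
}

# Deterministic climatological forcing for one month, repeated for `days`
# days: constant monthly-mean water temperature, the mid-month diurnal
# irradiance cycle at mean cloudiness, and the monthly rainfall spread
# uniformly. Used by scenario runs, which must be deterministic.
month_climatology <- function(month, days = 28, dt = 1800,
                              config = forcing_config()) {
  stopifnot(month %in% 1:12)
  steps_per_day <- round(SECONDS_PER_DAY / dt)
  doy_grid <- MONTH_MID_DOY[month] - 0.5 + seq(0, 1, length.out = 241)
  t_mean <- mean(water_temperature_climatology(doy_grid, config))
  hour <- (seq_len(steps_per_day) - 0.5) * dt / 3600
  i_day <- clear_sky_irradiance(MONTH_MID_DOY[month], hour, config) *
    config$cloud_mean
  n <- steps_per_day * days
  rain_per_step <- config$rain_monthly[month] /
    (DAYS_IN_MONTH[month] * steps_per_day)
  tibble::tibble(
    time = as.POSIXct("2021-01-01", tz = "UTC") + dt * (seq_len(n) - 1),
    t_water = t_mean,
    i_surface = rep(i_day, days),
    rainfall = rain_per_step,
    month = month
  )
}

# Monthly influent quality (mg/L) and dry-deposition loads (kg/month) of the
# historical replenishment source. Columns: nh4, no3, ip (mg/L), ss (mg/L),
# dep_nh4, dep_no3, dep_ip (kg/month).
influent_table <- function() {
  tibble::tibble(
    month = 1:12,
    nh4 = c(0.97, 0.80, 0.88, 0.83, 0.39, 0.76, 0.32, 0.68, 0.22, 0.58, 1.66, 1.69),
    no3 = c(2.89, 2.95, 2.86, 2.51, 1.66, 0.50, 0.53, 0.87, 0.66, 0.97, 0.78, 2.06),
    ip  = c(0.021, 0.027, 0.018, 0.012, 0.013, 0.041, 0.016, 0.014, 0.012, 0.010, 0.012, 0.045),
    ss  = c(12.62, 7.93, 12.69, 13.72, 16.61, 11.22, 14.31, 12.23, 13.18, 15.17, 9.92, 11.12),
    dep_nh4 = c(22.7, 20.5, 22.2, 20.4, 22.1, 12.6, 13.3, 13.5, 3.8, 5.7, 9.4, 25.4),
    dep_no3 = c(15.6, 14.1, 14.1, 13.0, 14.0, 5.0, 5.2, 5.3, 1.6, 2.4, 3.9, 17.4),
    dep_ip  = c(3.0, 2.7, 2.8, 2.5, 2.7, 1.8, 1.9, 1.9, 0.9, 1.3, 2.1, 3.3)
  )
}

#' Monthly influent quality
#'
#' Returns one month's influent concentrations for historical-mode simulation
#' (distinct from the surface-water/reclaimed-water scenario endmembers). The
#' suspended-solids column is split into an inorganic fraction (ISS) and an
#' organic remainder converted to detritus carbon.
#'
#' @param month Month number, 1-12.
#' @param iss_fraction Inorganic fraction of total suspended solids.
#' @param om_to_c Carbon content of the organic SS fraction (g C per g OM).
#' @return A list with `nh4`, `no3`, `ip`, `ss_total`, `iss`, `dc_in` (mg/L).
#' @examples
#' monthly_influent(1)$nh4 # 0.97
#' @export
monthly_influent <- function(month, iss_fraction = 0.75, om_to_c = 0.5) {
  if (length(month) != 1 || !month %in% 1:12) stop("month must be one of 1-12")
  if (iss_fraction < 0 || iss_fraction > 1) stop("iss_fraction must lie in [0, 1]")
  row <- influent_table()[month, ]
  list(nh4 = row$nh4, no3 = row$no3, ip = row$ip, ss_total = row$ss,
       iss = iss_fraction * row$ss,
       dc_in = (1 - iss_fraction) * row$ss * om_to_c)
}

#' Dry-deposition load rate
#'
#' Converts the monthly dry-deposition masses to constant daily load rates
#' (zero within-month variation).
#'
#' @param month Month number, 1-12.
#' @return Named vector `c(nh4=, no3=, ip=)` in g/day.
#' @examples
#' deposition_flux(1)[["nh4"]] # 22.7 kg over 31 days
#' @export
deposition_flux <- function(month) {
  if (length(month) != 1 || !month %in% 1:12) stop("month must be one of 1-12")
  row <- influent_table()[month, ]
  c(nh4 = row$dep_nh4, no3 = row$dep_no3, ip = row$dep_ip) * 1000 /
    DAYS_IN_MONTH[month]
}

#' External (non-point) load specification
#'
#' Impervious-surface runoff geometry and concentrations, plus the monthly
#' dry-deposition table.
#'
#' @param runoff_area Impervious catchment area (m²). Default 67000.
#' @param runoff_coefficient Fraction of rainfall converted to runoff, in
#'   (0, 1]. Default 0.9 (impervious pavement).
#' @param runoff_conc Named runoff concentrations (mg/L = g/m³).
#' @return A list of class `external_loads`.
#' @export
external_loads <- function(runoff_area = 67000, runoff_coefficient = 0.9,
                           runoff_conc = c(nh4 = 2.5, no3 = 4, ip = 0.64)) {
  if (runoff_coefficient <= 0 || runoff_coefficient > 1) {
    stop("runoff_coefficient must lie in (0, 1]")
  }
  if (runoff_area < 0) stop("runoff_area must be non-negative")
  structure(list(runoff_area = runoff_area,
                 runoff_coefficient = runoff_coefficient,
                 runoff_conc = runoff_conc),
            class = "external_loads")
}

#' Runoff volume and pollutant masses for one rainfall increment
#'
#' `volume = rainfall/1000 * area * coefficient`; each constituent mass is
#' `volume * concentration`.
#'
#' @param rainfall_mm Rainfall depth over the step (mm), non-negative.
#' @param loads An [external_loads()] specification.
#' @return A list with `volume` (m³) and `mass` (named vector, g).
#' @examples
#' runoff_load(10)$volume # 603 m3
#' @export
runoff_load <- function(rainfall_mm, loads = external_loads()) {
  if (any(rainfall_mm < 0)) stop("rainfall must be non-negative")
  volume <- rainfall_mm / 1000 * loads$runoff_area * loads$runoff_coefficient
  list(volume = volume,
       mass = sapply(loads$runoff_conc, function(conc) volume * conc))
}

#' Synthetic monthly pseudo-observations for calibration experiments
#'
#' Simulates a year of the lake under the historical monthly influent and a
#' constant total inflow with the supplied ("true") parameters, samples the
#' state mid-month (12 instants), and perturbs each sampled variable with
#' seeded multiplicative Gaussian noise of coefficient of variation
#' `noise_cv`. The noise-free truth is returned alongside for
#' parameter-recovery tests.
#'
#' @param true_params The [eco_params()] used as truth.
#' @param coeffs [optical_coefficients()].
#' @param seed Integer seed (drives both the forcing and the noise).
#' @param noise_cv Observation noise coefficient of variation (0 = exact).
#' @param q_total Constant total inflow (m³/s).
#' @param forcing Optional forcing tibble; defaults to
#'   `synth_forcing(days = 365, seed = seed)`.
#' @param geometry,loads Lake geometry and external loads.
#' @param iss_fraction Inorganic fraction of influent suspended solids.
#' @param dt Integration step (s).
#' @return A list with `observations` and `truth` (tibbles with one row per
#'   month and columns `month`, `time`, `sd_cm`, `chl`, `iss`, `nh4`, `no3`,
#'   `ip`), plus the `params`, `seed` and `q_total` used.
#' @export
synth_observations <- function(true_params = eco_params(),
                               coeffs = optical_coefficients(),
                               seed = 1, noise_cv = 0.1, q_total = 0.1,
                               forcing = NULL,
                               geometry = lake_geometry(),
                               loads = external_loads(),
                               iss_fraction = 0.75, dt = 1800) {
  if (is.null(forcing)) forcing <- synth_forcing(days = 365, dt = dt, seed = seed)
  truth <- simulate_observation_truth(true_params, coeffs, forcing, q_total,
                                      geometry, loads, iss_fraction, dt)
  obs <- truth
  if (noise_cv > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed + 1000L)
    vars <- c("sd_cm", "chl", "iss", "nh4", "no3", "ip")
    for (v in vars) {
      obs[[v]] <- pmax(obs[[v]] * (1 + noise_cv * rnorm(nrow(obs))), 1e-6)
    }
  }
  list(observations = obs, truth = truth, params = true_params,
       seed = seed, noise_cv = noise_cv, q_total = q_total)
}

# Run the historical-mode year and extract the mid-month sampled state.
# Shared by synth_observations() and calibrate() so both see one pipeline.
simulate_observation_truth <- function(params, coeffs, forcing, q_total,
                                       geometry = lake_geometry(),
                                       loads = external_loads(),
                                       iss_fraction = 0.75, dt = 1800) {
  make_monthly_predictor(forcing, q_total, coeffs, geometry, loads,
                         iss_fraction, dt)(params)
}

# 12-row inflow schedule (month, nh4, no3, ip, iss, dc_in) from the influent
# table.
influent_schedule <- function(iss_fraction = 0.75, om_to_c = 0.5) {
  tab <- influent_table()
  tibble::tibble(
    month = tab$month,
    nh4 = tab$nh4, no3 = tab$no3, ip = tab$ip,
    iss = iss_fraction * tab$ss,
    dc_in = (1 - iss_fraction) * tab$ss * om_to_c
  )
}
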