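# Process kinetics and the reference (pure-R) mass balance of the box model.
#
# The compiled simulation core in src/sim_core.cpp replicates
# lake_derivatives() term by term; keep the two in step. The R version is the
# documented reference used for single-point evaluation and for the
# independent-integrator cross-checks.

#' Temperature multiplier on growth
#'
#' Arrhenius-type factor `tetg^(T - 20)` referenced to 20 degC.
#'
#' @param t_water Water temperature (degC), in \[-2, 40\].
#' @param tetg Temperature theta (dimensionless).
#' @return Positive dimensionless multiplier.
#' @examples
#' temperature_factor(30) # 1.14^10
#' @export
temperature_factor <- function(t_water, tetg = 1.14) {
  if (any(!is.finite(t_water)) || any(t_water < -2) || any(t_water > 40)) {
    stop("t_water must lie in [-2, 40] degC")
  }
  tetg^(t_water - 20)
}

#' Nutrient colimitation factor
#'
#' Minimum-of-Monod colimitation: `min(DIN / (kn + DIN), ip / (kp + ip))`
#' with dissolved inorganic nitrogen DIN = nh4 + no3. Lies in \[0, 1\].
#'
#' @param nh4,no3 Ammonium and nitrate nitrogen (mg N/L).
#' @param ip Inorganic phosphorus (mg P/L).
#' @param kn,kp Half-saturation constants (mg N/L, mg P/L).
#' @return Dimensionless factor in \[0, 1\], vectorized.
#' @examples
#' nutrient_limitation(0.05, 0.10, 0.009) # min(0.75, 0.5)
#' @export
nutrient_limitation <- function(nh4, no3, ip, kn = 0.05, kp = 0.009) {
  if (any(c(nh4, no3, ip) < 0)) stop("nutrient concentrations must be non-negative")
  din <- nh4 + no3
  pmin(din / (kn + din), ip / (kp + ip))
}

#' Depth-averaged light limitation
#'
#' Monod response to irradiance, averaged analytically over a water column of
#' depth `depth` under exponential attenuation with coefficient `kd`:
#' `(1 / (kd * depth)) * log((i_k + I0) / (i_k + I0 * exp(-kd * depth)))`.
#' When `kd * depth` is (numerically) zero the surface response
#' `I0 / (i_k + I0)` is used.
#'
#' @param i_surface Surface irradiance I0 (W/m²), non-negative.
#' @param kd Diffuse attenuation (1/m), non-negative.
#' @param depth Water depth (m), non-negative.
#' @param i_k Light half-saturation (W/m²).
#' @return Dimensionless factor in \[0, 1\], vectorized over `i_surface`/`kd`.
#' @export
light_limitation <- function(i_surface, kd, depth, i_k = 80) {
  if (any(c(i_surface, kd, depth, i_k) < 0)) {
    stop("light_limitation arguments must be non-negative")
  }
  kdh <- kd * depth
  out <- ifelse(
    i_surface <= 0,
    0,
    ifelse(
      kdh > 1e-12,
      log((i_k + i_surface) / (i_k + i_surface * exp(-kdh))) / kdh,
      i_surface / (i_k + i_surface)
    )
  )
  as.numeric(out)
}

#' Time derivatives of the box-model state
#'
#' Completely mixed mass balance: for each constituent X,
#' `dX/dt = (Q_in X_in + Q_r X_r - Q_out X) / V + sources - sinks`, with the
#' outflow matching inflow plus runoff (fixed water level). Kinetic terms:
#' growth `mypc * f_T * f_I * f_nut * pc` (drawing ammonium first, then
#' nitrate, by `n_to_c`, and phosphorus by `p_to_c`), death `deac * pc` into
#' detritus, mineralization `kmdm * dc` releasing ammonium and phosphorus,
#' and settling `-(v / depth) * X` for ISS and detritus. Dry-deposition loads
#' enter as mass per volume per time.
#'
#' @param state A [lake_state()].
#' @param t_water Water temperature (degC).
#' @param i_surface Surface irradiance (W/m²).
#' @param inflow A [blend_sources()] result or any list with `nh4`, `no3`,
#'   `ip`, `iss`, `dc_in` (mg/L) giving the inflow concentrations.
#' @param q_total Total replenishment inflow (m³/s).
#' @param params An [eco_params()] set.
#' @param coeffs An [optical_coefficients()] set (drives self-shading via Kd).
#' @param geometry A [lake_geometry()].
#' @param deposition Named vector `c(nh4=, no3=, ip=)` of dry-deposition
#'   loads (g/day).
#' @param q_runoff Surface-runoff inflow (m³/day).
#' @param runoff_conc Named vector of runoff concentrations (g/m³).
#' @return Named numeric vector `d(pc, dc, iss, nh4, no3, ip)/dt` in
#'   mg/L per day.
#' @export
lake_derivatives <- function(state, t_water, i_surface, inflow, q_total,
                             params = eco_params(),
                             coeffs = optical_coefficients(),
                             geometry = lake_geometry(),
                             deposition = c(nh4 = 0, no3 = 0, ip = 0),
                             q_runoff = 0,
                             runoff_conc = c(nh4 = 2.5, no3 = 4, ip = 0.64)) {
  if (!inherits(state, "lake_state")) stop("state must be a lake_state")
  v <- geometry$volume
  h <- geometry$depth

  chl <- params$chl_to_c * state$pc
  a <- coeffs$a_w + coeffs$a_phi * chl + coeffs$a_iss * state$iss +
    coeffs$a_dc * state$dc
  b <- coeffs$b_w + coeffs$b_phi * chl + coeffs$b_iss * state$iss +
    coeffs$b_dc * state$dc
  kd <- diffuse_attenuation(a, b, coeffs$mu0)

  f_t <- temperature_factor(t_water, params$tetg)
  f_i <- light_limitation(i_surface, kd, h, params$i_k)
  f_nut <- nutrient_limitation(state$nh4, state$no3, state$ip,
                               params$kn, params$kp)

  growth <- params$mypc * f_t * f_i * f_nut * state$pc
  death <- params$deac * state$pc
  miner <- params$kmdm * params$tet_miner^(t_water - 20) * state$dc

  d_in <- q_total * SECONDS_PER_DAY / v     # 1/day
  d_r <- q_runoff / v
  d_out <- d_in + d_r

  din <- state$nh4 + state$no3
  f_pref <- if (din > 0) state$nh4 / (state$nh4 + params$nh4_pref) else 0

  c(
    pc = growth - death - d_out * state$pc,
    dc = death - miner + d_in * inflow$dc_in - d_out * state$dc -
      (params$v_settle_dc / h) * state$dc,
    iss = d_in * inflow$iss - d_out * state$iss -
      (params$v_settle_iss / h) * state$iss,
    nh4 = -growth * params$n_to_c * f_pref + miner * params$n_to_c +
      d_in * inflow$nh4 + d_r * runoff_conc[["nh4"]] - d_out * state$nh4 +
      deposition[["nh4"]] / v,
    no3 = -growth * params$n_to_c * (1 - f_pref) +
      d_in * inflow$no3 + d_r * runoff_conc[["no3"]] - d_out * state$no3 +
      deposition[["no3"]] / v,
    ip = -growth * params$p_to_c + miner * params$p_to_c +
      d_in * inflow$ip + d_r * runoff_conc[["ip"]] - d_out * state$ip +
      deposition[["ip"]] / v
  )
}

#' One explicit-Euler update of the lake state
#'
#' Advances the state by `dt` seconds using [lake_derivatives()], clipping any
#' small negative overshoots to zero (the number of clipped components is
#' attached as attribute `clipped`). A relative change above 50% in one step
#' for any bulk component (concentration above 1 mg/L; smaller values
#' sit near the clipping boundary, where drawdown and refill are legitimately
#' fast relative to the stock) raises an error
#' advising a smaller time step.
#'
#' @param state A [lake_state()].
#' @param dt Time step in seconds (default, and recommended maximum, 1800).
#' @param ... Passed to [lake_derivatives()].
#' @return The updated [lake_state()].
#' @export
lake_step <- function(state, dt = 1800, ...) {
  if (dt <= 0) stop("dt must be positive")
  if (dt > 1800) warning("dt above the recommended maximum of 1800 s")
  d <- lake_derivatives(state, ...)
  y <- state_vector(state)
  dt_days <- dt / SECONDS_PER_DAY
  step <- d * dt_days
  resolved <- y > 1
  if (any(abs(step[resolved]) > 0.5 * y[resolved])) {
    stop("unstable step: a constituent changed by more than 50% in one step; ",
         "reduce dt")
  }
  y_new <- y + step
  clipped <- sum(y_new < 0)
  y_new <- pmax(y_new, 0)
  out <- lake_state(pc = y_new[["pc"]], dc = y_new[["dc"]], iss = y_new[["iss"]],
                    nh4 = y_new[["nh4"]], no3 = y_new[["no3"]], ip = y_new[["ip"]],
                    chl_to_c = state$chl_to_c)
  attr(out, "clipped") <- clipped
  out
}
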