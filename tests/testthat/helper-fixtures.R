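# Shared fixtures: tiny parameter sets, forcing snippets and an independent
# one-expression Secchi-depth oracle.

# single-expression transparency oracle, written independently of the
# composed optics operations
sd_oracle <- function(chl, iss, dc, oc = optical_coefficients()) {
  a <- oc$a_w + oc$a_phi * chl + oc$a_iss * iss + oc$a_dc * dc
  b <- oc$b_w + oc$b_phi * chl + oc$b_iss * iss + oc$b_dc * dc
  kd <- a / oc$mu0 * sqrt(1 + (0.425 * oc$mu0 - 0.19) * b / a)
  oc$gamma / (a + b + kd)
}

# random physically plausible states under a fixed seed
random_states <- function(n, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    chl = runif(n, 0, 200),
    iss = runif(n, 0, 80),
    dc = runif(n, 0, 15)
  ))
}

# constant forcing snippet: steady temperature and irradiance, no rain
constant_forcing <- function(days, t_water = 20, i_surface = 200, dt = 1800) {
  n <- days * 86400 / dt
  tibble::tibble(
    time = as.POSIXct("2021-06-01", tz = "UTC") + dt * (seq_len(n) - 1),
    t_water = t_water,
    i_surface = i_surface,
    rainfall = 0
  )
}

# a closed-system configuration: no exchange, no settling, no loads
closed_params <- function(...) {
  eco_params(v_settle_iss = 0, v_settle_dc = 0, ...)
}

zero_inflow <- list(nh4 = 0, no3 = 0, ip = 0, iss = 0, dc_in = 0)

# flatten a lake_state into the integrator's state ordering
state_vector_for_test <- function(st) {
  c(pc = st$pc, dc = st$dc, iss = st$iss, nh4 = st$nh4, no3 = st$no3,
    ip = st$ip)
}

total_n <- function(sim, n_to_c = 0.18) {
  sim$nh4 + sim$no3 + n_to_c * (sim$pc + sim$dc)
}

total_p <- function(sim, p_to_c = 0.024) {
  sim$ip + p_to_c * (sim$pc + sim$dc)
}
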