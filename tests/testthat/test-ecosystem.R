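# Kinetic building blocks and the mass-balance integrator.

test_that("temperature factor matches direct evaluation and guards its domain", {
  expect_identical(temperature_factor(20), 1)
  expect_equal(temperature_factor(30, 1.14), 1.14^10)
  expect_equal(temperature_factor(10, 1.14), 1.14^-10)
  expect_error(temperature_factor(45), "40")
})

test_that("nutrient colimitation follows the minimum-of-Monod form", {
  # half-saturation definition: DIN = kn with plentiful P
  expect_equal(nutrient_limitation(0.025, 0.025, 10), 0.5)
  expect_identical(nutrient_limitation(0, 0, 5), 0)
  expect_equal(nutrient_limitation(0.05, 0.10, 0.009), min(0.75, 0.5))
  expect_error(nutrient_limitation(-0.1, 0, 0), "non-negative")
})

test_that("depth-averaged light limitation matches a numerical depth integral", {
  expect_identical(light_limitation(0, 1, 2), 0)
  expect_gt(light_limitation(1e9, 1, 2), 0.99)
  # kd -> 0 limit equals the surface Monod response
  expect_equal(light_limitation(150, 0, 2), 150 / (80 + 150))
  # independent oracle: numerical integration of the local Monod response
  numeric_avg <- function(i0, kd, h, ik = 80) {
    stats::integrate(function(z) {
      iz <- i0 * exp(-kd * z)
      iz / (ik + iz)
    }, 0, h)$value / h
  }
  for (case in list(c(100, 0.5, 2), c(640, 3.4, 2), c(50, 8, 1.5))) {
    expect_equal(light_limitation(case[1], case[2], case[3]),
                 numeric_avg(case[1], case[2], case[3]), tolerance = 1e-6)
  }
})

test_that("closed-system derivatives conserve nitrogen and phosphorus analytically", {
  st <- lake_state(chl = 40, dc = 3, iss = 10, nh4 = 0.4, no3 = 0.8, ip = 0.06)
  p <- closed_params()
  d <- lake_derivatives(st, t_water = 25, i_surface = 300, inflow = zero_inflow,
                        q_total = 0, params = p)
  expect_equal(d[["nh4"]] + d[["no3"]] + p$n_to_c * (d[["pc"]] + d[["dc"]]), 0,
               tolerance = 1e-14)
  expect_equal(d[["ip"]] + p$p_to_c * (d[["pc"]] + d[["dc"]]), 0,
               tolerance = 1e-14)
})

test_that("dark, nutrient-free water decays at exactly the death rate", {
  st <- lake_state(pc = 2, chl_to_c = 25)
  d <- lake_derivatives(st, t_water = 20, i_surface = 0, inflow = zero_inflow,
                        q_total = 0, params = closed_params())
  expect_equal(d[["pc"]], -0.10 * 2)
  expect_equal(d[["dc"]], 0.10 * 2)  # death feeds detritus
})

test_that("a conservative tracer reaches the influent concentration", {
  # ISS with settling disabled behaves as a conservative CSTR tracer
  p <- eco_params(v_settle_iss = 0)
  inflow <- list(nh4 = 0, no3 = 0, ip = 0, iss = 30, dc_in = 0)
  f <- constant_forcing(40, i_surface = 0)
  sim <- simulate_lake(lake_state(), f, inflow, q_total = 0.4, params = p,
                       loads = NULL)
  # HRT is V/Q ~ 5.8 d, so 40 days is about 7 e-folds
  expect_equal(tail(sim$iss, 1), 30, tolerance = 1e-3)
})

test_that("the Euler step is exact on fixed points and flags instability", {
  st <- lake_state(pc = 0, dc = 0, iss = 0, nh4 = 0, no3 = 0, ip = 0)
  new <- lake_step(st, dt = 1800, t_water = 20, i_surface = 0,
                   inflow = zero_inflow, q_total = 0, params = closed_params())
  expect_equal(state_vector_for_test(new), state_vector_for_test(st))
  # an absurdly large step on a fast-decaying constituent must be refused
  fast <- lake_state(pc = 5)
  expect_error(
    suppressWarnings(lake_step(fast, dt = 86400 * 20, t_water = 20,
                               i_surface = 0, inflow = zero_inflow,
                               q_total = 0)),
    "reduce dt")
})

test_that("dilution faster than maximal growth washes phytoplankton out", {
  # Q/V = 0.33/day against mypc * f_T(2 degC) ~ 0.26/day
  inflow <- blend_sources(p = 0.5)
  f <- constant_forcing(90, t_water = 2, i_surface = 300)
  sim <- simulate_lake(lake_state(chl = 50, iss = 20), f, inflow,
                       q_total = 0.77, loads = NULL)
  p <- eco_params()
  expect_gt(0.77 * 86400 / 200000, p$mypc * temperature_factor(2))
  expect_lt(tail(sim$pc, 1), 1e-3)
  expect_lt(tail(sim$chl, 1) / 50, 0.001)
})

test_that("closed-system nitrogen and phosphorus stay conserved over 30 days", {
  p <- closed_params()
  init <- lake_state(chl = 20, dc = 2, iss = 15, nh4 = 0.6, no3 = 1.2,
                     ip = 0.08)
  f <- constant_forcing(30, t_water = 22, i_surface = 250)
  sim <- simulate_lake(init, f, zero_inflow, q_total = 0, params = p,
                       loads = NULL)
  n <- total_n(sim, p$n_to_c)
  ptot <- total_p(sim, p$p_to_c)
  expect_lt(max(abs(n - n[1])) / n[1], 0.001)
  expect_lt(max(abs(ptot - ptot[1])) / ptot[1], 0.001)
})

test_that("halving the step changes a 30-day trajectory by less than 1%", {
  inflow <- blend_sources(p = 0.4)
  init <- lake_state(chl = 10, dc = 2, iss = 25, nh4 = 1, no3 = 2, ip = 0.2)
  run <- function(dt) {
    f <- constant_forcing(30, t_water = 12, i_surface = 180, dt = dt)
    simulate_lake(init, f, inflow, q_total = 0.2, dt = dt, loads = NULL)
  }
  a <- run(1800)
  b <- run(900)
  for (v in c("pc", "iss", "nh4", "no3", "ip", "sd")) {
    scale <- pmax(abs(b[[v]]), 0.01)
    expect_lt(max(abs(a[[v]] - b[[v]]) / scale), 0.01)
  }
})

test_that("the compiled core reproduces the reference R stepper", {
  inflow <- blend_sources(p = 0.6)
  init <- lake_state(chl = 15, dc = 1.5, iss = 20, nh4 = 0.8, no3 = 1.5,
                     ip = 0.15)
  f <- constant_forcing(3, t_water = 24, i_surface = 260)
  f$rainfall <- rep(c(0, 0.2), length.out = nrow(f))  # exercise runoff too
  cpp <- simulate_lake(init, f, inflow, q_total = 0.3, engine = "cpp")
  ref <- simulate_lake(init, f, inflow, q_total = 0.3, engine = "r")
  for (v in c("pc", "dc", "iss", "nh4", "no3", "ip", "sd")) {
    expect_equal(cpp[[v]], ref[[v]], tolerance = 1e-10)
  }
})

test_that("the Euler trajectory tracks an adaptive integrator within 1%", {
  skip_if_not_installed("deSolve")
  inflow <- blend_sources(p = 0.4)
  p <- eco_params()
  geom <- lake_geometry()
  rhs <- function(t, y, parms) {
    st <- lake_state(pc = y[1], dc = y[2], iss = y[3], nh4 = y[4],
                     no3 = y[5], ip = y[6], chl_to_c = p$chl_to_c)
    list(lake_derivatives(st, t_water = 24, i_surface = 260, inflow = inflow,
                          q_total = 0.25, params = p, geometry = geom))
  }
  init <- lake_state(chl = 10, dc = 2, iss = 25, nh4 = 1, no3 = 2, ip = 0.2)
  times <- seq(0, 10, by = 0.0625)  # 90-min output over 10 days
  ode <- deSolve::ode(state_vector_for_test(init), times, rhs, NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  f <- constant_forcing(10, t_water = 24, i_surface = 260)
  eul <- simulate_lake(init, f, inflow, q_total = 0.25, loads = NULL)
  for (k in 1:6) {
    ref <- ode[, k + 1]
    est <- eul[[c("pc", "dc", "iss", "nh4", "no3", "ip")[k]]]
    expect_lt(max(abs(est - ref) / pmax(abs(ref), 0.01)), 0.01)
  }
})

test_that("simulation output respects the 90-minute cadence contract", {
  f <- constant_forcing(2)
  sim <- simulate_lake(lake_state(chl = 5, iss = 10), f, zero_inflow,
                       q_total = 0.1, loads = NULL)
  expect_identical(nrow(sim), as.integer(2 * 86400 / 5400 + 1))
  expect_equal(diff(as.numeric(sim$time)), rep(5400, nrow(sim) - 1))
  # gap detection
  f_gap <- f[-10, ]
  expect_error(simulate_lake(lake_state(), f_gap, zero_inflow, q_total = 0.1),
               "gap")
})
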