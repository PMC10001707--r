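# Synthetic forcing, influent tables, deposition and runoff loads,
# pseudo-observations.

test_that("forcing generation is a pure function of config and seed", {
  a <- synth_forcing(days = 20, seed = 7)
  b <- synth_forcing(days = 20, seed = 7)
  expect_identical(a, b)
  c <- synth_forcing(days = 20, seed = 8)
  expect_false(identical(a$rainfall, c$rainfall))
})

test_that("the synthetic climate has the right seasonal and diurnal shape", {
  f <- synth_forcing(days = 365, seed = 1)
  mo <- as.integer(strftime(f$time, "%m", tz = "UTC"))
  t_mon <- tapply(f$t_water, mo, mean)
  expect_gt(t_mon[["7"]], t_mon[["1"]])
  expect_true(all(f$t_water >= 0 & f$t_water <= 35))
  expect_true(all(f$i_surface >= 0))
  # midnight irradiance is zero
  hour <- (as.numeric(f$time) %% 86400) / 3600
  expect_true(all(f$i_surface[hour < 0.5] == 0))
  # no gaps
  expect_true(all(diff(as.numeric(f$time)) == 1800))
})

test_that("annual rainfall reproduces the configured monthly totals", {
  cfg <- forcing_config()
  f <- synth_forcing(days = 365, seed = 3, config = cfg)
  mo <- as.integer(strftime(f$time, "%m", tz = "UTC"))
  totals <- as.numeric(tapply(f$rainfall, mo, sum))
  expect_equal(totals, cfg$rain_monthly, tolerance = 1e-9)
  clim <- synth_forcing(days = 365, seed = 1, climatology = TRUE)
  mo <- as.integer(strftime(clim$time, "%m", tz = "UTC"))
  expect_equal(as.numeric(tapply(clim$rainfall, mo, sum)), cfg$rain_monthly,
               tolerance = 1e-9)
})

test_that("monthly influent rows match the boundary-condition table", {
  jan <- monthly_influent(1)
  expect_equal(jan$nh4, 0.97)
  expect_equal(jan$no3, 2.89)
  expect_equal(jan$ip, 0.021)
  expect_equal(jan$ss_total, 12.62)
  expect_equal(monthly_influent(12)$nh4, 1.69)
  for (m in 1:12) {
    row <- monthly_influent(m)
    expect_true(all(unlist(row) >= 0))
    expect_lte(row$iss, row$ss_total)
  }
  expect_error(monthly_influent(13), "month")
})

test_that("deposition fluxes divide monthly masses into constant daily rates", {
  expect_equal(deposition_flux(1)[["nh4"]], 22.7 * 1000 / 31)
  expect_equal(deposition_flux(2)[["ip"]], 2.7 * 1000 / 28)
  # annual ammonium deposition adds back to the table total
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  annual <- sum(vapply(1:12, function(m) deposition_flux(m)[["nh4"]] * days[m],
                       numeric(1)))
  expect_equal(annual, 191.6 * 1000)
})

test_that("runoff volume and mass follow the runoff-coefficient arithmetic", {
  r0 <- runoff_load(0)
  expect_identical(r0$volume, 0)
  expect_true(all(r0$mass == 0))
  r <- runoff_load(10)
  expect_equal(r$volume, 0.010 * 67000 * 0.9)  # 603 m3
  expect_equal(r$mass[["nh4"]], 603 * 2.5)     # 1507.5 g
  # linear in rainfall
  expect_equal(runoff_load(20)$mass[["ip"]], 2 * r$mass[["ip"]])
})

test_that("pseudo-observations are reproducible and collapse to truth at zero noise", {
  a <- synth_observations(seed = 5, noise_cv = 0.1)
  b <- synth_observations(seed = 5, noise_cv = 0.1)
  expect_identical(a$observations, b$observations)
  expect_identical(nrow(a$observations), 12L)
  exact <- synth_observations(seed = 5, noise_cv = 0)
  expect_identical(exact$observations, exact$truth)
  # noisy observations differ from truth but stay positive
  expect_false(any(a$observations$chl == a$truth$chl))
  expect_true(all(a$observations$chl > 0))
})
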