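# Component-wise absorption/scattering, Kirk's Kd and the Secchi-depth
# composition.

test_that("absorption and scattering reproduce hand-evaluated sums", {
  # pure-water limits
  expect_equal(absorption(list(chl = 0, iss = 0, dc = 0)), 0.050)
  expect_equal(scattering(list(chl = 0, iss = 0, dc = 0)), 0.0019)
  # hand evaluation with the calibrated coefficient set
  expect_equal(absorption(list(chl = 10, iss = 20, dc = 1)),
               0.050 + 0.020 * 10 + 0.08 * 20 + 0.24 * 1)
  expect_equal(scattering(list(chl = 0, iss = 31, dc = 0)),
               0.0019 + 0.025 * 31)
  # linearity: doubling all constituents doubles the constituent part
  s1 <- list(chl = 7, iss = 13, dc = 2)
  s2 <- list(chl = 14, iss = 26, dc = 4)
  expect_equal(absorption(s2) - 0.050, 2 * (absorption(s1) - 0.050))
  expect_equal(scattering(s2) - 0.0019, 2 * (scattering(s1) - 0.0019))
})

test_that("negative concentrations are rejected naming the constituent", {
  expect_error(absorption(list(chl = -1, iss = 0, dc = 0)), "chl")
  expect_error(scattering(list(chl = 0, iss = -2, dc = 0)), "iss")
  expect_error(secchi_depth(list(chl = 0, iss = 0, dc = -0.1)), "dc")
})

test_that("beam attenuation is the exact sum of absorption and scattering", {
  expect_identical(beam_attenuation(0.050, 0.0019), 0.0519)
  expect_identical(beam_attenuation(2.090, 0.7769), 2.8669)
  expect_identical(beam_attenuation(0, 0), 0)
  expect_error(beam_attenuation(-1, 0), "non-negative")
})

test_that("Kirk's diffuse attenuation matches its collapse cases", {
  # b = 0 collapses to a / mu0
  for (mu0 in c(0.5, 0.856, 1)) {
    expect_equal(diffuse_attenuation(0.3, 0, mu0), 0.3 / mu0)
  }
  # hand evaluation at mu0 = 1
  expect_equal(diffuse_attenuation(0.050, 0.0019, mu0 = 1),
               0.050 * sqrt(1 + 0.235 * 0.0019 / 0.050))
  # monotone non-decreasing in b at fixed a, mu0
  b_grid <- seq(0, 5, by = 0.25)
  kd <- vapply(b_grid, function(b) diffuse_attenuation(1.2, b, 0.856),
               numeric(1))
  expect_true(all(diff(kd) >= 0))
  # Kd >= a whenever mu0 <= 1
  states <- random_states(50)
  a <- absorption(states); b <- scattering(states)
  expect_true(all(diffuse_attenuation(a, b, 0.856) >= a))
})

test_that("diffuse attenuation rejects degenerate inputs", {
  expect_error(diffuse_attenuation(0, 1), "positive")
  expect_error(diffuse_attenuation(1, 1, mu0 = 0), "mu0")
  expect_error(diffuse_attenuation(1, 1, mu0 = 1.2), "mu0")
  # mu0 below 0.19/0.425 makes the radicand negative for large b/a
  expect_error(diffuse_attenuation(0.05, 10, mu0 = 0.3), "radicand")
})

test_that("secchi_depth agrees with the single-expression oracle to 1e-12", {
  states <- random_states(200)
  expect_equal(secchi_depth(states), sd_oracle(states$chl, states$iss, states$dc),
               tolerance = 1e-12)
  oc <- optical_coefficients(b_phi = 0.06, mu0 = 0.9, gamma = 8.9)
  expect_equal(secchi_depth(states, oc),
               sd_oracle(states$chl, states$iss, states$dc, oc),
               tolerance = 1e-12)
})

test_that("secchi depth decreases in every constituent and vanishes in the limit", {
  base <- random_states(25, seed = 7)
  for (var in c("chl", "iss", "dc")) {
    bumped <- base
    bumped[[var]] <- bumped[[var]] + 5
    expect_true(all(secchi_depth(bumped) < secchi_depth(base)))
  }
  # componentwise-larger state has smaller SD
  larger <- base
  larger$chl <- base$chl + 1; larger$iss <- base$iss + 2; larger$dc <- base$dc + 0.5
  expect_true(all(secchi_depth(larger) <= secchi_depth(base)))
  # constituents to infinity: SD to 0+
  expect_lt(secchi_depth(list(chl = 1e7, iss = 1e7, dc = 1e7)), 1e-4)
  expect_gt(secchi_depth(list(chl = 1e7, iss = 1e7, dc = 1e7)), 0)
})

test_that("optical budget satisfies its internal identities", {
  states <- random_states(40, seed = 11)
  ob <- optical_budget(states)
  expect_identical(ob$c, ob$a + ob$b)
  expect_true(all(ob$sd > 0))
  expect_equal(ob$sd, 8.9 / (ob$c + ob$kd))
})

test_that("coefficient validation enforces the physical domain", {
  expect_error(optical_coefficients(gamma = -1))
  expect_error(optical_coefficients(mu0 = 0))
  expect_error(optical_coefficients(a_w = -0.1))
  expect_message(optical_coefficients(verbose = TRUE), "defaults")
})
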