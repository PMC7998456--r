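test_that("circadian surge factor has the right shape and peak", {
  pd <- pd_parameters()
  expect_equal(circadian_factor(22.38, pd), 1 + 28.48, tolerance = 1e-12)
  ## direct evaluation of the quartic bell away from the peak
  expect_equal(circadian_factor(12, pd),
               1 + 28.48 / ((10.38 / 0.99)^4 + 1), tolerance = 1e-12)
  ## zero amplitude switches the surge off entirely
  pd0 <- pd_parameters(MA = 0)
  tt <- seq(0, 48, by = 0.25)
  expect_true(all(circadian_factor(tt, pd0) == 1))
  ## 24-h wrap: same clock time on consecutive days, factor >= 1 everywhere,
  ## maximal at the peak time
  f <- circadian_factor(tt, pd)
  expect_equal(circadian_factor(tt + 24, pd), f, tolerance = 1e-12)
  expect_true(all(f >= 1))
  expect_true(all(f <= circadian_factor(pd$MTmax, pd) + 1e-12))
})

test_that("meal dilution factor matches its closed form and recurs daily", {
  pd <- pd_parameters()
  expect_identical(food_effect(2, pd), 1)
  expect_equal(food_effect(4, pd), 1 / (1 + 40.04), tolerance = 1e-12)
  expect_equal(food_effect(10, pd),
               1 / (1 + 40.04 * exp(-0.64 * 6) + 97.7), tolerance = 1e-12)
  tt <- seq(0, 24, by = 0.05)
  fe <- food_effect(tt, pd)
  expect_true(all(fe > 0 & fe <= 1))
  expect_identical(fe[tt < 4], rep(1, sum(tt < 4)))
  ## monotone recovery toward 1 between and after meals
  expect_true(all(diff(fe[tt >= 4 & tt < 10]) >= 0))
  expect_true(all(diff(fe[tt >= 10]) >= 0))
  ## daily recurrence on multi-day horizons
  expect_equal(food_effect(tt + 24, pd), fe, tolerance = 1e-12)
  expect_error(food_effect(-1, pd), "t >= 0")
})

test_that("meal dilution lowers observed H+ and raises pH as expected", {
  pd <- pd_parameters()
  expect_identical(observed_h(0.033, 1), 0.033)
  expect_equal(observed_h(0.033, 0.5), 0.0165)
  ## chained example: dilution right after lunch lifts pH by ~1.6 units
  fe4 <- food_effect(4, pd)
  expect_equal(ph_from_h(observed_h(0.033, fe4)) - ph_from_h(0.033),
               -log10(fe4), tolerance = 1e-12)
  expect_equal(-log10(fe4), 1.613, tolerance = 1e-3)
  expect_error(observed_h(-1, 1), "positive")
  expect_error(observed_h(1, 1.5), "Fe")
})

test_that("pH conversion is the exact inverse pair on the mM scale", {
  expect_identical(ph_from_h(1), 0)
  expect_equal(ph_from_h(0.033), 1.4815, tolerance = 1e-4)
  for (x in c(1e-4, 0.033, 10))
    expect_equal(h_from_ph(ph_from_h(x)), x, tolerance = 1e-12)
  expect_error(ph_from_h(0), "positive")
  expect_error(ph_from_h(-2), "positive")
})

test_that("parameter containers validate their invariants", {
  expect_error(pk_parameters(CLp = -1), "CLp")
  expect_error(pk_parameters(theta_sex = 0), "theta_sex")
  expect_error(pd_parameters(kdeg = 0), "kdeg")
  expect_error(pd_parameters(MTmax = 25), "MTmax")
  expect_error(pd_parameters(omega = c(kdeg = -0.1, kd = 1, kout = 1)),
               "omega")
  ## omegas given unnamed are matched positionally; missing names become 0
  pk <- pk_parameters(omega = c(CLp = 0.3))
  expect_identical(unname(pk$omega[c("CLt", "Vc", "Vt")]), c(0, 0, 0))
})
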