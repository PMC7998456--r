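test_that("closed-form concentration agrees with stiff ODE integration", {
  set.seed(42)
  reg <- regimen(dose_event(c(0, 24, 48), c(20, 10, 10)), horizon = 72)
  tt <- c(0.25, 0.5, 0.6, 1, 2, 5, 8, 12, 23.9, 24.6, 30, 47, 50, 71)
  for (i in 1:5) {
    pki <- c(CLp = runif(1, 1, 6), CLt = runif(1, 1, 8),
             Vc = runif(1, 4, 15), Vt = runif(1, 2, 10))
    cf <- pk_concentration(tt, reg, pki)
    od <- pk_ode_oracle(tt, reg$events, pki)
    expect_equal(cf, od, tolerance = 1e-6)
  }
})

test_that("concentration is zero before dosing and linear in dose", {
  pki <- individual_parameters(pk_parameters(), 70, 0)
  reg <- regimen(dose_event(2, 10), horizon = 24)
  tt <- seq(0, 24, by = 0.5)
  cp <- pk_concentration(tt, reg, pki)
  expect_identical(cp[tt <= 2], rep(0, sum(tt <= 2)))
  ## exact dose-proportionality (superposition of a linear system)
  reg2 <- regimen(dose_event(2, 20), horizon = 24)
  expect_equal(pk_concentration(tt, reg2, pki), 2 * cp, tolerance = 1e-12)
})

test_that("multi-dose profile equals superposed shifted single doses", {
  pki <- individual_parameters(pk_parameters(), 62, 1)
  multi <- daily_regimen(c(20, 10, 10))
  tt <- seq(0, 72, by = 0.25)
  cp_multi <- pk_concentration(tt, multi, pki)
  cp_sum <- pk_concentration(tt, regimen(dose_event(0, 20), horizon = 72), pki) +
    pk_concentration(tt, regimen(dose_event(24, 10), horizon = 72), pki) +
    pk_concentration(tt, regimen(dose_event(48, 10), horizon = 72), pki)
  expect_equal(cp_multi, cp_sum, tolerance = 1e-12)
})

test_that("analytic AUC equals dose/clearance and matches quadrature", {
  pki <- individual_parameters(pk_parameters(), 70, 0)
  reg <- regimen(dose_event(0, 10), horizon = 24)
  expect_equal(pk_auc_inf(reg, pki), 10 / 2.57 * 1000, tolerance = 1e-12)
  ## numerical quadrature of the simulated curve over a long horizon
  tt <- seq(0, 200, by = 0.02)
  cp <- pk_concentration(tt, reg, pki)
  auc_num <- sum(diff(tt) * (head(cp, -1) + tail(cp, -1)) / 2)
  expect_equal(auc_num, pk_auc_inf(reg, pki), tolerance = 1e-4)
})

test_that("covariate model scales individual parameters correctly", {
  pk <- pk_parameters()
  p <- individual_parameters(pk, 70, 0)
  expect_equal(unname(p), c(2.57, 4.59, 8.80, 3.65))
  ## allometric weight on Vc
  p2 <- individual_parameters(pk, 62.6, 0)
  expect_equal(unname(p2[["Vc"]]), 8.80 * (62.6 / 70)^1.35, tolerance = 1e-12)
  expect_equal(unname(p2[["Vc"]]), 7.57, tolerance = 1e-2)
  ## sex multiplier on clearance
  p3 <- individual_parameters(pk, 70, 1)
  expect_equal(unname(p3[["CLp"]]), 2.57 * 1.30, tolerance = 1e-12)
  ## random effects act log-normally
  p4 <- individual_parameters(pk, 70, 0, eta = c(log(2), 0, 0, 0))
  expect_equal(unname(p4[["CLp"]]), 2 * 2.57, tolerance = 1e-12)
  expect_error(individual_parameters(pk, -5, 0), "weight")
  expect_error(individual_parameters(pk, 70, 2), "sex")
})

test_that("dose events and regimens enforce their invariants", {
  expect_error(dose_event(0, -5), "amount")
  expect_error(dose_event(0, 5, 0), "duration")
  expect_error(regimen(dose_event(0, 5), horizon = 0.2), "horizon")
  r <- daily_regimen(c(20, 10, 10))
  expect_equal(r$events$start_time, c(0, 24, 48))
  expect_equal(r$horizon, 72)
  ## events sorted regardless of construction order
  r2 <- regimen(dose_event(24, 10), dose_event(0, 20))
  expect_equal(r2$events$start_time, c(0, 24))
})
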