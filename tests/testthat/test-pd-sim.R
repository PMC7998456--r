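test_that("drug-free system without surge stays at its fixed point", {
  pd <- pd_parameters(MA = 0)
  b <- baseline_profile(pd, horizon = 72, grid = seq(0, 72, 0.5))
  expect_true(all(b$Cp == 0))
  expect_true(all(abs(b$E - 1) < 1e-10))
  expect_true(all(abs(b$H - pd$HBASE) < 1e-10 * pd$HBASE))
})

test_that("simulated trajectories match an independent stiff integration", {
  pk <- pk_parameters()
  pd <- pd_parameters()
  pki <- individual_parameters(pk, 65, 1)
  reg <- regimen(dose_event(0, 20), horizon = 24)
  grid <- seq(0.5, 24, by = 0.5)
  sim <- simulate_individual(reg, pki, pd, grid = grid, dt = 0.01)
  cp_fn <- function(tt) pk_concentration(tt, reg, pki) / 1000
  orc <- pd_ode_oracle(grid, cp_fn, pd)
  expect_equal(sim$E, orc$E, tolerance = 1e-4)
  expect_equal(sim$H, orc$H, tolerance = 1e-4)
  ## and with individual PD random effects (slower pump, slower washout)
  eta <- c(-0.5, 0.3, -0.7)
  sim2 <- simulate_individual(reg, pki, pd, grid = grid, eta_pd = eta,
                              dt = 0.01)
  orc2 <- pd_ode_oracle(grid, cp_fn, pd, eta_pd = eta)
  expect_equal(sim2$H, orc2$H, tolerance = 1e-4)
})

test_that("pump activity stays within (0, 1] for any non-negative input", {
  pk <- pk_parameters()
  pd <- pd_parameters()
  set.seed(7)
  for (i in 1:6) {
    pki <- individual_parameters(pk, runif(1, 45, 85), rbinom(1, 1, 0.5),
                                 rnorm(4, 0, 0.4))
    dose <- sample(c(0, 5, 20, 80), 1)
    sim <- simulate_individual(daily_regimen(rep(dose, 3)), pki, pd,
                               grid = seq(0, 72, 0.25),
                               eta_pd = rnorm(3, 0, 0.5))
    expect_true(all(sim$E > 0 & sim$E <= 1 + 1e-12))
    expect_true(all(sim$H > 0))
    expect_true(all(is.finite(sim$pH)))
  }
})

test_that("acid suppression is delayed relative to the plasma rise", {
  ## indirect response: the pH half-rise lags the concentration half-rise
  ## (pre-meal window, so meals do not confound the comparison)
  pki <- individual_parameters(pk_parameters(), 70, 0)
  sim <- simulate_individual(regimen(dose_event(0, 20), horizon = 24), pki,
                             pd_parameters(), grid = seq(0, 3.9, 0.02))
  t50_cp <- min(sim$time[sim$Cp >= 0.5 * max(sim$Cp)])
  rise <- sim$pH - sim$pH[1]
  t50_ph <- min(sim$time[rise >= 0.5 * max(rise)])
  expect_gt(t50_ph, t50_cp + 0.2)
})

test_that("pH response is monotone non-decreasing in dose", {
  pki <- individual_parameters(pk_parameters(), 70, 0)
  pd <- pd_parameters()
  grid <- seq(0, 24, 0.25)
  sims <- lapply(c(10, 20, 40), function(d)
    simulate_individual(regimen(dose_event(0, d), horizon = 24), pki, pd,
                        grid = grid))
  expect_true(all(sims[[2]]$pH >= sims[[1]]$pH - 1e-9))
  expect_true(all(sims[[3]]$pH >= sims[[2]]$pH - 1e-9))
})

test_that("zero-dose simulation reproduces the drug-free baseline", {
  pd <- pd_parameters()
  pki <- individual_parameters(pk_parameters(), 70, 0)
  reg <- regimen(dose_event(0, 0), label = "none", horizon = 24)
  sim <- simulate_individual(reg, pki, pd, grid = seq(0, 24, 0.25))
  base <- baseline_profile(pd, horizon = 24, grid = seq(0, 24, 0.25))
  expect_equal(sim$pH, base$pH, tolerance = 1e-12)
  expect_true(all(sim$E == 1))
  ## meal discontinuities visible at 12:00 and 18:00 clock (t = 4, 10)
  expect_gt(sim$pH[sim$time == 4] - sim$pH[sim$time == 3.75], 1)
  expect_gt(sim$pH[sim$time == 10] - sim$pH[sim$time == 9.75], 0.5)
})

test_that("simulation rejects invalid grids and reports integrator issues", {
  pki <- individual_parameters(pk_parameters(), 70, 0)
  reg <- regimen(dose_event(0, 10), horizon = 24)
  expect_error(simulate_individual(reg, pki, pd_parameters(),
                                   grid = c(3, 1, 2)), "sorted")
  expect_error(simulate_individual(reg, pki, pd_parameters(),
                                   grid = c(0, 30)), "horizon")
})
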