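test_that("virtual populations hit the configured demographics", {
  pop <- sample_population(2000, demographics_simulation(), seed = 1)
  expect_equal(sum(pop$SEX), 1000L)
  expect_true(all(pop$WT >= 40 & pop$WT <= 80))
  expect_true(median(pop$WT) > 68 && median(pop$WT) < 72)
  ## reproducible single subject
  expect_identical(sample_population(1, seed = 5),
                   sample_population(1, seed = 5))
  ## median over seeds concentrates near the configured centre
  med <- vapply(1:10, function(s)
    median(sample_population(500, demographics_simulation(), seed = s)$WT),
    numeric(1))
  expect_true(abs(mean(med) - 70) < 2)
  expect_error(demographics(70, 8, 80, 40), "bounds")
})

test_that("degenerate variability collapses the trial to the typical curve", {
  pk0 <- pk_novar(0)
  pd0 <- pd_novar(0)
  subj <- sample_population(3, demographics_internal(), seed = 2)
  subj$WT <- 70  # identical covariates so all subjects are the typical one
  subj$SEX <- 0L
  reg <- regimen(dose_event(0, 10), horizon = 24)
  sch <- trial_schedule(24, ph = seq(0, 24, 1))
  ds <- simulate_trial(subj, reg, pk0, pd0, schedule = sch, seed = 3,
                       with_noise = FALSE)
  r <- ds$records
  pki <- individual_parameters(pk0, 70, 0)
  typ <- simulate_individual(reg, pki, pd0, grid = seq(0, 24, 1), dt = 0.025)
  for (id in 1:3) {
    ph <- r[r$ID == id & r$DVTYPE == 2 & r$MDV == 0, ]
    expect_equal(ph$DV, typ$pH, tolerance = 1e-10)
  }
})

test_that("residual error magnitudes match the generating model", {
  ## proportional concentration error: empirical CV of replicated noisy
  ## observations at a fixed concentration
  pk <- pk_parameters()
  subj <- sample_population(1, demographics_internal(), seed = 4)
  subj <- draw_random_effects(subj, pk, pd_parameters(), seed = 4)
  reg <- regimen(dose_event(0, 10), horizon = 24)
  sch <- trial_schedule(24, conc = rep(2, 400), ph = numeric(0))
  ## many replicate samples at t = 2 h: unique-key rule forbids this in a
  ## dataset, so sample the noise model directly through simulate_trial on
  ## individually jittered times
  sch$conc <- seq(1.99, 2.01, length.out = 400)
  ds <- simulate_trial(subj, reg, pk, NULL, schedule = sch, seed = 5)
  o <- conc_obs(ds)
  expect_equal(sd(o$DV) / mean(o$DV), 0.12, tolerance = 0.15)
  ## additive pH error: unclipped Gaussian with the configured SD
  ## (fresh covariate-only subject so no stored random effects interfere)
  subj_plain <- subj[, c("ID", "WT", "SEX")]
  sch2 <- trial_schedule(24, conc = numeric(0), ph = seq(0, 24, 0.05))
  ds2 <- simulate_trial(subj_plain, reg, pk_novar(0.0), pd_novar(1.28),
                        schedule = sch2, seed = 6)
  ph <- ds2$records[ds2$records$DVTYPE == 2, ]
  pki <- individual_parameters(pk_novar(0), subj$WT, subj$SEX)
  truth <- simulate_individual(reg, pki, pd_novar(0), grid = sch2$ph)
  resid <- ph$DV - truth$pH
  expect_equal(mean(resid), 0, tolerance = 0.15)
  expect_equal(sd(resid), 1.28, tolerance = 0.08)
})

test_that("trial simulation is reproducible and subject-prefix stable", {
  pk <- pk_parameters()
  pd <- pd_parameters()
  a <- generate_internal_study(pk, pd, seed = 9, ph_by = 4)
  b <- generate_internal_study(pk, pd, seed = 9, ph_by = 4)
  expect_identical(a$records, b$records)
  ## same seed, larger trial: leading subjects identical
  h <- generate_loading_dose_study(pk, pd, seed = 3, population = "healthy",
                                   ph_by = 6)
  u <- generate_loading_dose_study(pk, pd, seed = 3, population = "ulcer",
                                   ph_by = 6)
  expect_identical(u$records, h$records[h$records$ID <= 10, ])
})

test_that("pH trajectory metrics are exact on analytic inputs", {
  tt <- seq(0, 24, 0.25)
  m <- regimen_metrics(tt, rep(7, length(tt)))
  expect_equal(m$mean_ph, 7)
  expect_equal(m$pct_above6, 100)
  expect_equal(m$nocturnal_pct_above4, 100)
  ## step series above threshold for half the window: exact up to the
  ## trapezoid's half-interval attribution at the crossing
  step <- ifelse(tt < 12, 5, 3)
  expect_lt(abs(regimen_metrics(tt, step)$pct_above4 - 50),
            100 * 0.125 / 24 + 1e-9)
  ## drug-free baseline: meals cannot push pH above 6
  b <- baseline_profile(pd_parameters(), horizon = 24)
  mb <- regimen_metrics(b$time, b$pH)
  expect_equal(mb$pct_above6, 0)
  expect_lt(mb$mean_ph, 2.5)
  ## incomplete window is flagged missing, not extrapolated
  m2 <- regimen_metrics(tt, step, windows = list(day2 = c(24, 48)))
  expect_true(is.na(m2$mean_ph))
})

test_that("percentile bands are ordered and collapse without variability", {
  pk <- pk_parameters()
  pd <- pd_parameters()
  subj <- sample_population(40, demographics_simulation(), seed = 11)
  subj <- draw_random_effects(subj, pk, pd, seed = 12)
  cur <- ppipkpd:::.population_curves(subj, daily_regimen(20), pk, pd,
                                      grid_step = 1)
  b <- ppipkpd:::.bands(cur$time, cur$ph)
  expect_true(all(b$p5 <= b$p50 & b$p50 <= b$p95))
  ## no variability: bands coincide with the typical curve
  subj0 <- draw_random_effects(sample_population(5, seed = 1),
                               pk_novar(0), pd_novar(0), seed = 1)
  subj0$WT <- 70; subj0$SEX <- 0L
  cur0 <- ppipkpd:::.population_curves(subj0, daily_regimen(20),
                                       pk_novar(0), pd_novar(0),
                                       grid_step = 1)
  b0 <- ppipkpd:::.bands(cur0$time, cur0$ph)
  expect_equal(b0$p5, b0$p95, tolerance = 1e-12)
})
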