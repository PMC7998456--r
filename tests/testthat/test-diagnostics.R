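test_that("VPC is seed-reproducible and detects misspecification", {
  pk <- pk_parameters()
  pd <- NULL  # concentration-only VPC keeps this test fast
  ds <- generate_internal_study(seed = 8, ph_by = 24)
  ds$records <- ds$records[ds$records$DVTYPE != 2, ]
  v1 <- vpc(ds, pk, pd, n_rep = 60, seed = 3)
  v2 <- vpc(ds, pk, pd, n_rep = 60, seed = 3)
  expect_identical(v1$bins, v2$bins)
  expect_true(all(v1$bins$sim_p5 <= v1$bins$sim_p50 &
                    v1$bins$sim_p50 <= v1$bins$sim_p95))
  ## doubling clearance halves exposure: simulated median band drops below
  ## the observations and coverage collapses
  pk_bad <- pk_parameters(CLp = 2 * 2.57, Vc = 2 * 8.80)
  v_bad <- vpc(ds, pk_bad, pd, n_rep = 60, seed = 3)
  expect_lt(v_bad$coverage$overall, v1$coverage$overall)
  late <- v1$bins$TIME >= 4
  expect_true(mean(v_bad$bins$sim_p50[late] < v1$bins$obs_p50[late]) > 0.8)
})

test_that("single-replicate VPC bands equal that replicate's percentiles", {
  ds <- generate_internal_study(seed = 8, ph_by = 24)
  ds$records <- ds$records[ds$records$DVTYPE != 2, ]
  v <- vpc(ds, pk_parameters(), NULL, n_rep = 1, seed = 4)
  expect_equal(v$n_rep, 1)
  expect_true(all(is.finite(v$bins$sim_p50)))
  expect_true(all(v$bins$env_p50_lo == v$bins$env_p50_hi))
})

test_that("goodness-of-fit residuals behave on well-specified data", {
  ## perfect noiseless fit: all residuals vanish
  pk0 <- pk_novar(0)
  subj <- sample_population(4, demographics_internal(), seed = 12)
  reg <- regimen(dose_event(0, 10), horizon = 24)
  ds0 <- simulate_trial(subj, reg, pk0, NULL,
                        schedule = trial_schedule(24, ph = numeric(0)),
                        seed = 13, with_noise = FALSE)
  fit0 <- suppressWarnings(fit_pk(ds0, compute_se = FALSE))
  g0 <- gof(ds0, fit0)
  expect_lt(max(abs(g0$table$RES)) / max(g0$table$DV), 0.01)
  ## proportional-error data without BSV: weighted residuals ~ N(0, 1)
  pk_n <- pk_novar(0.12)
  ds1 <- simulate_trial(sample_population(12, demographics_internal(),
                                          seed = 14),
                        reg, pk_n, NULL,
                        schedule = trial_schedule(24, ph = numeric(0)),
                        seed = 15)
  fit1 <- suppressWarnings(fit_pk(ds1, init = pk_n, compute_se = FALSE,
                                  control = list(iter.max = 60)))
  g1 <- gof(ds1, fit1)
  expect_equal(mean(g1$table$WRES), 0, tolerance = 0.15)
  expect_equal(sd(g1$table$WRES), 1, tolerance = 0.2)
  ## with BSV, individual predictions track data better than population ones
  pk_b <- pk_parameters(omega = c(CLp = 0.3, CLt = 0.2, Vc = 0.15,
                                  Vt = 0.2), sigma_prop = 0.08)
  ds2 <- simulate_trial(sample_population(8, demographics_internal(),
                                          seed = 16),
                        reg, pk_b, NULL,
                        schedule = trial_schedule(24, ph = numeric(0)),
                        seed = 17)
  fit2 <- suppressWarnings(fit_pk(ds2, init = pk_b, compute_se = FALSE,
                                  control = list(iter.max = 60)))
  g2 <- gof(ds2, fit2)
  expect_lt(g2$summary$rmse_ipred, g2$summary$rmse_pred)
})

test_that("external validation covers same-model data and flags shifts", {
  pk <- pk_parameters()
  pd <- pd_parameters()
  ext <- generate_external_30mg(pk, pd, seed = 18, ph_by = 3)
  ev <- external_validation(ext, pk, pd, n_rep = 60, seed = 19)
  expect_gt(ev$coverage$overall, 0.75)
  expect_true(all(c("sim_p5", "sim_p50", "sim_p95", "inside") %in%
                    names(ev$records)))
  ## a strongly shifted model loses coverage
  pk_shift <- pk_parameters(CLp = 3 * 2.57)
  ev2 <- external_validation(ext, pk_shift, pd, n_rep = 60, seed = 19)
  expect_lt(ev2$coverage$by_type[["1"]], ev$coverage$by_type[["1"]] - 0.2)
  ## an empty external dataset is a clean error
  empty <- ext
  empty$records <- empty$records[empty$records$MDV == 1, ]
  expect_error(external_validation(empty, pk, pd), "no observations")
})
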