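test_that("objective equals the exact -2 log-likelihood without random effects", {
  pk <- pk_parameters(omega = c(CLp = 0, CLt = 0, Vc = 0, Vt = 0),
                      sigma_prop = 0.12)
  subj <- sample_population(1, demographics_internal(), seed = 2)
  reg <- regimen(dose_event(0, 10), horizon = 24)
  ds <- simulate_trial(subj, reg, pk, NULL,
                       schedule = trial_schedule(24, ph = numeric(0)),
                       seed = 3)
  ofv <- marginal_objective(ds, pk_model_spec(), pk)
  o <- conc_obs(ds)
  pki <- individual_parameters(pk, o$WT[1], o$SEX[1])
  f <- pk_concentration(o$TIME, reg, pki)
  manual <- sum(log(2 * pi * (0.12 * f)^2) + (o$DV - f)^2 / (0.12 * f)^2)
  expect_equal(ofv, manual, tolerance = 1e-10)
})

test_that("Laplace and FOCE objectives match adaptive quadrature on a one-eta subject", {
  pk <- pk_parameters(omega = c(CLp = 0.3, CLt = 0, Vc = 0, Vt = 0),
                      sigma_prop = 0.1)
  reg <- regimen(dose_event(0, 10), horizon = 24)
  ds <- simulate_trial(sample_population(1, demographics_internal(),
                                         seed = 5),
                       reg, pk, NULL,
                       schedule = trial_schedule(24, conc = c(1, 8),
                                                 ph = numeric(0)),
                       seed = 6)
  spec <- pk_model_spec(bsv = "CLp")
  exact <- quadrature_ofv_1eta(conc_obs(ds), reg, pk, 0.3)
  expect_lt(abs(marginal_objective(ds, spec, pk, method = "foce") - exact),
            0.1)
  expect_lt(abs(marginal_objective(ds, spec, pk, method = "laplace") - exact),
            0.1)
})

test_that("objective is invariant to subject order and design time shifts", {
  pk <- pk_parameters(omega = c(CLp = 0.3, CLt = 0.2, Vc = 0.1, Vt = 0.2),
                      sigma_prop = 0.1)
  subj <- sample_population(4, demographics_internal(), seed = 7)
  reg <- regimen(dose_event(0, 10), horizon = 24)
  ds <- simulate_trial(subj, reg, pk, NULL,
                       schedule = trial_schedule(24, ph = numeric(0)),
                       seed = 8)
  ofv <- marginal_objective(ds, pk_model_spec(), pk)
  ## relabel subjects in reverse order
  rec <- ds$records
  rec$ID <- 5L - rec$ID
  expect_equal(marginal_objective(study_dataset(rec), pk_model_spec(), pk),
               ofv, tolerance = 1e-8)
  ## shift the whole design (doses and samples) by +6 h
  rec2 <- ds$records
  rec2$TIME <- rec2$TIME + 6
  expect_equal(marginal_objective(study_dataset(rec2), pk_model_spec(), pk),
               ofv, tolerance = 1e-8)
})

test_that("noiseless zero-BSV data identify the PK fixed effects exactly", {
  pk0 <- pk_novar(0)
  subj <- sample_population(4, demographics_internal(), seed = 1)
  ds <- simulate_trial(subj, regimen(dose_event(0, 10), horizon = 24), pk0,
                       NULL, schedule = trial_schedule(24, ph = numeric(0)),
                       seed = 2, with_noise = FALSE)
  fit <- suppressWarnings(fit_pk(ds, compute_se = FALSE))
  expect_equal(fit$estimates$CLp, 2.57, tolerance = 0.01)
  expect_equal(fit$estimates$CLt, 4.59, tolerance = 0.01)
  expect_equal(fit$estimates$Vc, 8.80, tolerance = 0.01)
  expect_equal(fit$estimates$Vt, 3.65, tolerance = 0.01)
  expect_equal(fit$estimates$theta_wt, 1.35, tolerance = 0.02)
  expect_equal(fit$estimates$theta_sex, 1.30, tolerance = 0.01)
})

test_that("noiseless zero-BSV pH data identify the PD fixed effects", {
  pk0 <- pk_novar(0)
  pd0 <- pd_novar(0)
  subj <- sample_population(6, demographics_internal(), seed = 1)
  ds <- simulate_trial(subj, regimen(dose_event(0, 20), horizon = 24), pk0,
                       pd0, schedule = trial_schedule(24,
                                                      ph = seq(0, 24, 0.5)),
                       seed = 2, with_noise = FALSE)
  pki <- pk_individual_true(pk0, ds$subjects)
  init <- pd_parameters(kdeg = 0.3, kd = 10, kout = 3, FE4h = 20,
                        FE10h = 50, kFE = 1,
                        omega = c(kdeg = 0.2, kd = 0.2, kout = 0.2),
                        sigma_add = 0.5)
  fit <- suppressWarnings(fit_pd_sequential(ds, pki, init = init,
                                            compute_se = FALSE))
  expect_equal(fit$estimates$kdeg, 0.15, tolerance = 0.02)
  expect_equal(fit$estimates$kout, 5.6, tolerance = 0.02)
  expect_equal(fit$estimates$FE4h, 40.04, tolerance = 0.02)
  expect_equal(fit$estimates$FE10h, 97.7, tolerance = 0.02)
  expect_equal(fit$estimates$kFE, 0.64, tolerance = 0.02)
  ## the inhibition efficacy is the least curved direction of the fit:
  ## identified to within ~10% from 30-min pH sampling
  expect_equal(fit$estimates$kd, 18.24, tolerance = 0.1)
})

test_that("empirical Bayes estimates behave like posterior modes", {
  pk <- pk_parameters(omega = c(CLp = 0.3, CLt = 0.2, Vc = 0.15, Vt = 0.2),
                      sigma_prop = 0.08)
  subj <- sample_population(4, demographics_internal(), seed = 9)
  subj <- draw_random_effects(subj, pk, pd_parameters(), seed = 10)
  reg <- regimen(dose_event(0, 10), horizon = 24)
  ds <- simulate_trial(subj, reg, pk, NULL,
                       schedule = trial_schedule(24, ph = numeric(0)),
                       seed = 11)
  eb <- empirical_bayes(ds, pk_model_spec(), pk)
  ## rich-data subjects: EBEs track the generating etas
  expect_equal(eb$eta_CLp, subj$eta_CLp, tolerance = 0.15)
  ## degenerate prior: omega -> 0 forces etas to 0
  pk_tiny <- pk_parameters(omega = c(CLp = 1e-9, CLt = 1e-9, Vc = 1e-9,
                                     Vt = 1e-9), sigma_prop = 0.08)
  eb0 <- empirical_bayes(ds, pk_model_spec(), pk_tiny)
  expect_true(all(abs(as.matrix(eb0[, -1])) < 1e-6))
  ## a subject with no observations sits at the prior mode
  rec <- ds$records
  rec <- rec[!(rec$ID == 2 & rec$MDV == 0), ]
  eb2 <- empirical_bayes(study_dataset(rec), pk_model_spec(), pk)
  expect_true(all(eb2[eb2$ID == 2, -1] == 0))
})

test_that("eta magnitudes shrink as individual data vanish", {
  pk <- pk_parameters(omega = c(CLp = 0.4, CLt = 0, Vc = 0, Vt = 0),
                      sigma_prop = 0.1)
  subj <- sample_population(1, demographics_internal(), seed = 20)
  subj <- draw_random_effects(subj, pk, pd_parameters(), seed = 20)
  subj$eta_CLp <- 0.6  # a strongly deviating subject
  reg <- regimen(dose_event(0, 10), horizon = 24)
  rich <- simulate_trial(subj, reg, pk, NULL,
                         schedule = trial_schedule(24, ph = numeric(0)),
                         seed = 21)
  sparse <- rich
  keep <- rich$records$MDV == 1 | rich$records$TIME %in% c(1, 12)
  sparse <- study_dataset(rich$records[keep, ])
  eb_rich <- empirical_bayes(rich, pk_model_spec(bsv = "CLp"), pk)
  eb_sparse <- empirical_bayes(sparse, pk_model_spec(bsv = "CLp"), pk)
  expect_gt(abs(eb_rich$eta_CLp), abs(eb_sparse$eta_CLp) * 0.9)
  expect_equal(unname(eb_rich$eta_CLp), 0.6, tolerance = 0.25)
})

test_that("AIC ranking identifies structure and covariates on synthetic data", {
  ## data generated from the 2-compartment covariate model
  pk <- pk_parameters(omega = c(CLp = 0.2, CLt = 0.2, Vc = 0.1, Vt = 0.2),
                      sigma_prop = 0.08)
  subj <- sample_population(10, demographics_internal(), seed = 30)
  reg <- regimen(dose_event(0, 10), horizon = 24)
  ds <- simulate_trial(subj, reg, pk, NULL,
                       schedule = trial_schedule(24, ph = numeric(0)),
                       seed = 31)
  ctrl <- list(iter.max = 80)
  fit2 <- suppressWarnings(fit_pk(ds, init = pk, compute_se = FALSE,
                                  control = ctrl))
  fit1 <- suppressWarnings(fit_pk(ds, spec = pk_model_spec(n_compartments = 1),
                                  compute_se = FALSE, control = ctrl))
  cmp <- model_compare(two_cmt = fit2, one_cmt = fit1)
  expect_equal(cmp$model[1], "two_cmt")
  expect_gt(cmp$delta_aic[2], 10)
  expect_equal(cmp$delta_aic[1], 0)
  ## dropping the true covariates costs AIC
  fit_nocov <- suppressWarnings(
    fit_pk(ds, spec = pk_model_spec(covariate_wt = FALSE,
                                    covariate_sex = FALSE),
           compute_se = FALSE, control = ctrl))
  cmp2 <- model_compare(cov = fit2, nocov = fit_nocov)
  expect_equal(cmp2$model[1], "cov")
  ## identical fits tie at delta 0
  cmp3 <- model_compare(a = fit2, b = fit2)
  expect_equal(cmp3$delta_aic, c(0, 0))
  ## fits on different datasets are rejected
  ds2 <- simulate_trial(subj, reg, pk, NULL,
                        schedule = trial_schedule(24, ph = numeric(0)),
                        seed = 99)
  fit_other <- suppressWarnings(fit_pk(ds2, init = pk, compute_se = FALSE,
                                       control = ctrl))
  expect_error(model_compare(a = fit2, b = fit_other), "same dataset")
})

test_that("standard errors and CIs are reported on the natural scale", {
  pk <- pk_parameters(omega = c(CLp = 0.2, CLt = 0.2, Vc = 0.1, Vt = 0.2),
                      sigma_prop = 0.08)
  subj <- sample_population(6, demographics_internal(), seed = 40)
  ds <- simulate_trial(subj, regimen(dose_event(0, 10), horizon = 24), pk,
                       NULL, schedule = trial_schedule(24, ph = numeric(0)),
                       seed = 41)
  fit <- suppressWarnings(fit_pk(ds, init = pk, compute_se = TRUE,
                                 control = list(iter.max = 60)))
  expect_false(is.null(fit$se_table))
  tab <- fit$se_table
  expect_true(all(tab$lo95 <= tab$estimate & tab$estimate <= tab$hi95))
  expect_true(all(tab$se > 0))
  expect_equal(fit$aic, fit$ofv + 2 * fit$n_par)
})
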