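#' Generate the internal crossover study (16 subjects, IV 5/10/20 mg)
#'
#' Emulates the model-building study: 16 healthy subjects (1:1 male:female,
#' weight truncated-normal 62.6 +/- 8.0 kg, range 52-79 kg), each receiving
#' single IV infusions of 5, 10 and 20 mg on three crossover occasions with
#' 24-h plasma sampling and intragastric pH-metry. Occasions share each
#' subject's random-effect vector (no inter-occasion variability) and are
#' independent 24-h timelines (the 1-week washout leaves no carryover). The
#' 10 mg oral arm of the original design is excluded: the model has no
#' absorption component.
#'
#' @param pk,pd generating population parameters
#' @param seed integer seed (all weights, random effects and residual noise
#'   derive from it; generation is subject-sequential, so prefixes agree
#'   across sample sizes)
#' @param doses infusion amounts (mg), one per occasion
#' @param n number of subjects
#' @param ph_by pH sampling interval (h)
#' @param infusion_duration infusion length (h)
#' @param with_noise emit residual error (default) or noiseless model values
#' @param dt PD integration step (h)
#' @return A [study_dataset()] with a generation manifest.
#' @examples
#' \donttest{
#' ds <- generate_internal_study(seed = 1)
#' ds
#' }
#' @export
generate_internal_study <- function(pk = pk_parameters(), pd = pd_parameters(),
                                    seed = 1, doses = c(5, 10, 20), n = 16,
                                    ph_by = 0.25, infusion_duration = 0.5,
                                    with_noise = TRUE, dt = 0.025) {
  .with_seed(seed, {
    subjects <- sample_population(n, demographics_internal())
    regs <- lapply(doses, function(d)
      regimen(dose_event(0, d, infusion_duration),
              label = paste0(d, " mg IV"), horizon = 24))
    sch <- trial_schedule(24, ph = seq(0, 24, by = ph_by))
    ds <- simulate_trial(subjects, regs, pk, pd, schedule = sch,
                         with_noise = with_noise, dt = dt,
                         label = "internal crossover study (synthetic)")
    ds$manifest <- modifyList(ds$manifest,
                              list(study = "internal", seed = seed, doses = doses,
                          ph_by = ph_by, infusion_duration = infusion_duration,
                          demographics = unclass(demographics_internal()),
                          pk = unclass(pk), pd = unclass(pd)))
    ds
  })
}

#' Generate the external single-dose 30 mg study (10 subjects)
#'
#' Emulates the external-validation study: 10 healthy subjects receiving a
#' single 30 mg infusion at 08:00 with 24-h monitoring.
#'
#' @inheritParams generate_internal_study
#' @param dose infusion amount (mg)
#' @return A [study_dataset()].
#' @export
generate_external_30mg <- function(pk = pk_parameters(), pd = pd_parameters(),
                                   seed = 1, dose = 30, n = 10,
                                   ph_by = 0.25, infusion_duration = 0.5,
                                   with_noise = TRUE, dt = 0.025) {
  .with_seed(seed, {
    subjects <- sample_population(n, demographics_internal())
    reg <- regimen(dose_event(0, dose, infusion_duration),
                   label = paste0(dose, " mg IV"), horizon = 24)
    sch <- trial_schedule(24, ph = seq(0, 24, by = ph_by))
    ds <- simulate_trial(subjects, reg, pk, pd, schedule = sch,
                         with_noise = with_noise, dt = dt,
                         label = "external 30 mg study (synthetic)")
    ds$manifest <- modifyList(ds$manifest,
                              list(study = "external_30mg", seed = seed, dose = dose,
                          ph_by = ph_by, pk = unclass(pk), pd = unclass(pd)))
    ds
  })
}

#' Generate a loading-dose study (20 mg then 10 mg daily, 72 h)
#'
#' Emulates the multiple-dose validation studies: 20 mg at 08:00 on day 1
#' followed by 10 mg once daily on days 2 and 3, with plasma and pH
#' monitoring over 72 h. The duodenal-ulcer population uses the same model
#' parameters as healthy subjects (their PK and acid-inhibition profiles are
#' similar) and differs only in sample size and label.
#'
#' @inheritParams generate_internal_study
#' @param population `"healthy"` (n = 12) or `"ulcer"` (n = 10)
#' @param amounts daily dose amounts (mg)
#' @return A [study_dataset()].
#' @export
generate_loading_dose_study <- function(pk = pk_parameters(),
                                        pd = pd_parameters(), seed = 1,
                                        population = c("healthy", "ulcer"),
                                        amounts = c(20, 10, 10),
                                        ph_by = 0.25,
                                        infusion_duration = 0.5,
                                        with_noise = TRUE, dt = 0.025) {
  population <- match.arg(population)
  n <- if (population == "healthy") 12L else 10L
  .with_seed(seed, {
    ## both populations subset a common 12-subject pool so that, at the same
    ## seed, the ulcer dataset is exactly the first 10 subjects of the
    ## healthy one
    subjects <- head(sample_population(12L, demographics_internal()), n)
    reg <- daily_regimen(amounts, infusion_duration,
                         label = paste(amounts, collapse = "/"))
    sch <- trial_schedule(reg$horizon, ph = seq(0, reg$horizon, by = ph_by))
    ds <- simulate_trial(subjects, reg, pk, pd, schedule = sch,
                         with_noise = with_noise, dt = dt,
                         label = sprintf("loading-dose study, %s (synthetic)",
                                         population))
    ds$manifest <- modifyList(ds$manifest,
                              list(study = paste0("loading_", population), seed = seed,
                          amounts = amounts, ph_by = ph_by,
                          pk = unclass(pk), pd = unclass(pd)))
    ds
  })
}
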