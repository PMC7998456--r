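#' Observation schedules for simulated trials
#'
#' Default sampling: plasma at 0 (pre-dose, non-informative), 0.25, 0.5,
#' 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12 and 24 h after each dose start; pH every
#' 15 min (continuous pH-metry emulation).
#'
#' @param conc plasma sampling times (h)
#' @param ph pH sampling times (h)
#' @param horizon horizon the schedule is built for (h)
#' @return A `trial_schedule` list.
#' @export
trial_schedule <- function(horizon = 24,
                           conc = NULL, ph = NULL) {
  if (is.null(conc)) {
    offsets <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 12)
    days <- seq(0, by = 24, length.out = max(1, horizon %/% 24))
    conc <- sort(unique(pmin(c(outer(offsets, days, `+`), horizon), horizon)))
  }
  if (is.null(ph)) ph <- seq(0, horizon, by = 0.25)
  structure(list(conc = conc, ph = ph, horizon = horizon),
            class = "trial_schedule")
}

#' Simulate a population trial dataset
#'
#' Samples per-subject random effects (log-normal BSV), simulates each
#' subject under the regimen(s), and emits a [study_dataset()] with
#' proportional residual error on concentrations (`y = Cp (1 + eps)`) and
#' additive error on pH (`y = pH + eps`). Randomness is consumed
#' subject-by-subject, so with a fixed seed the first `k` subjects of a
#' larger trial reproduce a smaller one exactly.
#'
#' pH observations are stored as generated (additive noise is not clipped to
#' physical pH bounds); summary metrics are intended to be computed on
#' noiseless curves.
#'
#' @param subjects tibble with `ID`, `WT`, `SEX` (see [sample_population()]);
#'   may already carry `eta_*` columns to reuse random effects across arms
#' @param regimen a [regimen()] or a list of regimens treated as crossover
#'   occasions sharing each subject's random effects
#' @param pk a [pk_parameters()]
#' @param pd a [pd_parameters()]; `NULL` simulates concentrations only
#' @param schedule a [trial_schedule()] (recycled per occasion)
#' @param seed optional seed
#' @param with_noise logical; `FALSE` emits noiseless model values as DV
#' @param dt PD integration step (h)
#' @param label dataset label
#' @return A [study_dataset()]. Pre-dose concentration records (model value
#'   exactly 0) are emitted with `MDV = 1`. The returned object additionally
#'   carries `$subjects`, the subject table with the generating random
#'   effects (the simulation truth; not written to CSV) — this is what
#'   allows sequential PD estimation conditional on the true individual PK.
#' @export
simulate_trial <- function(subjects, regimen, pk, pd = NULL,
                           schedule = NULL, seed = NULL, with_noise = TRUE,
                           dt = 0.025, label = "simulated trial") {
  stopifnot(inherits(pk, "pk_parameters"))
  regs <- if (inherits(regimen, "regimen")) list(regimen) else regimen
  stopifnot(all(vapply(regs, inherits, TRUE, "regimen")))
  if (is.null(schedule)) schedule <- trial_schedule(regs[[1L]]$horizon)
  scheds <- if (inherits(schedule, "trial_schedule")) {
    rep(list(schedule), length(regs))
  } else schedule
  .with_seed(seed, {
    rec <- vector("list", nrow(subjects))
    eta_tab <- matrix(0, nrow(subjects), 7,
                      dimnames = list(NULL, c("eta_CLp", "eta_CLt", "eta_Vc",
                                              "eta_Vt", "eta_kdeg", "eta_kd",
                                              "eta_kout")))
    has_eta <- all(c("eta_CLp") %in% names(subjects))
    for (i in seq_len(nrow(subjects))) {
      s <- subjects[i, ]
      eta_pk <- if (has_eta) {
        c(s$eta_CLp, s$eta_CLt, s$eta_Vc, s$eta_Vt)
      } else .draw_eta(pk$omega)
      eta_pd <- if (!is.null(pd)) {
        if (has_eta && "eta_kdeg" %in% names(subjects)) {
          c(s$eta_kdeg, s$eta_kd, s$eta_kout)
        } else .draw_eta(pd$omega)
      } else numeric(3)
      eta_tab[i, ] <- c(eta_pk, eta_pd)
      pk_i <- individual_parameters(pk, s$WT, s$SEX, eta_pk)
      occ_rec <- vector("list", length(regs))
      for (k in seq_along(regs)) {
        reg <- regs[[k]]
        sch <- scheds[[k]]
        cp <- pk_concentration(sch$conc, reg, pk_i)
        eps <- if (with_noise) rnorm(length(cp), 0, pk$sigma_prop) else 0
        conc_rows <- tibble::tibble(
          ID = s$ID, OCC = k, TIME = sch$conc, AMT = 0, DUR = 0,
          DV = ifelse(cp > 0, cp * (1 + eps), NA_real_),
          DVTYPE = 1L, MDV = as.integer(cp <= 0), WT = s$WT, SEX = s$SEX)
        ph_rows <- NULL
        if (!is.null(pd) && length(sch$ph)) {
          sim <- simulate_individual(reg, pk_i, pd, grid = sch$ph,
                                     eta_pd = eta_pd, dt = dt)
          eph <- if (with_noise) rnorm(length(sch$ph), 0, pd$sigma_add) else 0
          ph_rows <- tibble::tibble(
            ID = s$ID, OCC = k, TIME = sch$ph, AMT = 0, DUR = 0,
            DV = sim$pH + eph, DVTYPE = 2L, MDV = 0L, WT = s$WT, SEX = s$SEX)
        }
        dose_rows <- tibble::tibble(
          ID = s$ID, OCC = k, TIME = reg$events$start_time,
          AMT = reg$events$amount, DUR = reg$events$duration,
          DV = NA_real_, DVTYPE = 0L, MDV = 1L, WT = s$WT, SEX = s$SEX)
        occ_rec[[k]] <- rbind(dose_rows, conc_rows, ph_rows)
      }
      rec[[i]] <- do.call(rbind, occ_rec)
    }
    ds <- study_dataset(do.call(rbind, rec), label = label,
                        manifest = list(label = label, seed = seed,
                                        n = nrow(subjects),
                                        regimens = lapply(regs, function(r)
                                          r$label),
                                        with_noise = with_noise))
    ## the generating per-subject random effects (simulation truth; enables
    ## PD estimation conditional on the true individual PK)
    ds$subjects <- tibble::as_tibble(cbind(
      subjects[, c("ID", "WT", "SEX")], tibble::as_tibble(eta_tab)))
    ds
  })
}

#' Acid-suppression summary metrics of a pH trajectory
#'
#' Time-weighted (trapezoidal) 24-h window metrics: mean pH, percentage of
#' time with pH above 4 and above 6, and the nocturnal (20:00-08:00, i.e.
#' 12-24 h after the 08:00 dose) percentage of time above 4. Windows without
#' full grid coverage yield `NA` rather than extrapolated values.
#'
#' @param time trajectory times (h, sorted)
#' @param ph pH values on `time`
#' @param windows named list of `c(start, end)` windows (h); default: each
#'   complete 24-h day covered by the grid
#' @return Tibble with one row per window: `window`, `start`, `end`,
#'   `mean_ph`, `pct_above4`, `pct_above6`, `nocturnal_pct_above4`.
#' @export
regimen_metrics <- function(time, ph, windows = NULL) {
  stopifnot(length(time) == length(ph), !is.unsorted(time))
  if (is.null(windows)) {
    ndays <- floor((max(time) + 1e-9) / 24)
    windows <- lapply(seq_len(max(ndays, 1L)),
                      function(d) c(24 * (d - 1), 24 * d))
    names(windows) <- paste0("day", seq_along(windows))
  }
  out <- lapply(names(windows), function(w) {
    a <- windows[[w]][1L]; b <- windows[[w]][2L]
    noct <- c(a + 12, a + 24)  # clock 20:00 -> 08:00 for an 08:00 dose
    tibble::tibble(
      window = w, start = a, end = b,
      mean_ph = .trapz_mean(time, ph, a, b),
      pct_above4 = 100 * .trapz_mean(time, as.numeric(ph > 4), a, b),
      pct_above6 = 100 * .trapz_mean(time, as.numeric(ph > 6), a, b),
      nocturnal_pct_above4 =
        100 * .trapz_mean(time, as.numeric(ph > 4), noct[1L], noct[2L]))
  })
  do.call(rbind, out)
}

## Trapezoidal mean of y over [a, b]; NA when the grid does not cover the
## window (no extrapolation).
.trapz_mean <- function(t, y, a, b) {
  if (min(t) > a + 1e-9 || max(t) < b - 1e-9) return(NA_real_)
  keep <- t >= a - 1e-9 & t <= b + 1e-9
  tt <- t[keep]; yy <- y[keep]
  if (length(tt) < 2L) return(NA_real_)
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2) / (max(tt) - min(tt))
}

## Percentile bands of a subjects-by-time value matrix.
.bands <- function(time, mat, probs = c(0.05, 0.5, 0.95)) {
  qs <- apply(mat, 2, quantile, probs = probs, names = FALSE)
  tibble::tibble(time = time, p5 = qs[1, ], p50 = qs[2, ], p95 = qs[3, ])
}

## Shared engine: noiseless per-subject Cp and pH curves for one regimen.
## Returns list(time, cp = n x T matrix, ph = n x T matrix).
.population_curves <- function(subjects, reg, pk, pd, grid_step = 0.25,
                               dt = 0.025) {
  grid <- seq(0, reg$horizon, by = grid_step)
  n <- nrow(subjects)
  cp <- matrix(NA_real_, n, length(grid))
  ph <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    s <- subjects[i, ]
    pk_i <- individual_parameters(pk, s$WT, s$SEX,
                                  c(s$eta_CLp, s$eta_CLt, s$eta_Vc, s$eta_Vt))
    sim <- simulate_individual(reg, pk_i, pd, grid = grid,
                               eta_pd = c(s$eta_kdeg, s$eta_kd, s$eta_kout),
                               dt = dt)
    cp[i, ] <- sim$Cp
    ph[i, ] <- sim$pH
  }
  list(time = grid, cp = cp, ph = ph)
}

#' Attach sampled random effects to a subject table
#'
#' Draws each subject's log-scale PK and PD random effects from the omega
#' values of `pk`/`pd` and stores them as `eta_*` columns, so several
#' simulated arms can share subject-level variability (paired comparison).
#'
#' @inheritParams simulate_trial
#' @return `subjects` with eight additional `eta_*` columns.
#' @export
draw_random_effects <- function(subjects, pk, pd, seed = NULL) {
  .with_seed(seed, {
    n <- nrow(subjects)
    epk <- matrix(rnorm(4 * n, 0, rep(pk$omega, each = n)), n, 4)
    epd <- matrix(rnorm(3 * n, 0, rep(pd$omega, each = n)), n, 3)
    subjects$eta_CLp <- epk[, 1]; subjects$eta_CLt <- epk[, 2]
    subjects$eta_Vc <- epk[, 3]; subjects$eta_Vt <- epk[, 4]
    subjects$eta_kdeg <- epd[, 1]; subjects$eta_kd <- epd[, 2]
    subjects$eta_kout <- epd[, 3]
    subjects
  })
}

#' Dose-ceiling analysis
#'
#' Simulates multi-day once-daily dosing at several dose levels over a
#' shared virtual population (identical random effects across dose arms) and
#' summarizes the dose-response of exposure and acid suppression: median
#' Cmax per dose (linear PK makes it proportional to dose) and median
#' per-day pH metrics, together with the incremental gains between adjacent
#' dose levels.
#'
#' @param doses dose levels (mg), once daily
#' @param days number of dosing days
#' @param n number of virtual subjects
#' @param pk,pd population parameters
#' @param demo demographics for [sample_population()]
#' @param seed seed for subjects and random effects
#' @param grid_step output grid resolution (h)
#' @param dt PD integration step (h)
#' @return List with `summary` (per dose and day: median metrics), `cmax`
#'   (per dose: median Cmax and ratio to the lowest dose), `gains` (between
#'   adjacent doses on the final day), `bands` (per-dose 5/50/95 pH bands)
#'   and `ceiling_ratio` (final-day mean-pH gain of the top dose step
#'   relative to the bottom step).
#' @export
ceiling_analysis <- function(doses = c(10, 20, 30, 40), days = 3, n = 2000,
                             pk = pk_parameters(), pd = pd_parameters(),
                             demo = demographics_simulation(), seed = 1,
                             grid_step = 0.25, dt = 0.025) {
  subjects <- sample_population(n, demo, seed = seed)
  subjects <- draw_random_effects(subjects, pk, pd, seed = seed + 1L)
  per_dose <- lapply(doses, function(d) {
    reg <- daily_regimen(rep(d, days), label = paste0(d, " mg qd"))
    cur <- .population_curves(subjects, reg, pk, pd, grid_step, dt)
    metr <- lapply(seq_len(n), function(i)
      cbind(ID = i, regimen_metrics(cur$time, cur$ph[i, ])))
    metr <- do.call(rbind, metr)
    med <- do.call(rbind, lapply(split(metr, metr$window), function(m)
      tibble::tibble(dose = d, window = m$window[1L],
                     median_mean_ph = median(m$mean_ph),
                     median_pct_above4 = median(m$pct_above4),
                     median_pct_above6 = median(m$pct_above6))))
    cmax <- apply(cur$cp, 1, max)
    list(summary = med,
         cmax = tibble::tibble(dose = d, median_cmax = median(cmax)),
         bands = cbind(dose = d, .bands(cur$time, cur$ph)))
  })
  summary <- do.call(rbind, lapply(per_dose, `[[`, "summary"))
  cmax <- do.call(rbind, lapply(per_dose, `[[`, "cmax"))
  cmax$ratio_to_lowest <- cmax$median_cmax / cmax$median_cmax[1L]
  final <- summary[summary$window == paste0("day", days), ]
  final <- final[order(final$dose), ]
  gains <- tibble::tibble(
    step = paste(head(final$dose, -1), tail(final$dose, -1), sep = "->"),
    gain_mean_ph = diff(final$median_mean_ph),
    gain_pct_above6 = diff(final$median_pct_above6))
  ceiling_ratio <- if (nrow(final) >= 3) {
    (final$median_mean_ph[nrow(final)] - final$median_mean_ph[2L]) /
      (final$median_mean_ph[2L] - final$median_mean_ph[1L])
  } else NA_real_
  list(summary = summary, cmax = cmax, gains = gains,
       bands = do.call(rbind, lapply(per_dose, `[[`, "bands")),
       ceiling_ratio = ceiling_ratio)
}

#' Compare dosing regimens on acid-suppression metrics
#'
#' Simulates each regimen over a shared virtual population (paired
#' subject-level random effects remove between-arm Monte-Carlo noise by
#' default) and summarizes per-day and whole-horizon pH metrics plus
#' exposure per day.
#'
#' @param regimens named list of [regimen()] objects
#'   (default [reference_regimens()])
#' @param n number of virtual subjects
#' @param pk,pd population parameters
#' @param demo demographics
#' @param seed seed
#' @param shared_eta share random effects across regimens (paired design)
#' @param grid_step,dt grid resolutions (h)
#' @return List with `summary` (per regimen and day: median mean pH,
#'   %time>4, %time>6, median day Cmax), `overall` (per regimen: median mean
#'   pH over the horizon) and `bands` (per-regimen pH percentile bands).
#' @export
compare_regimens <- function(regimens = reference_regimens(), n = 2000,
                             pk = pk_parameters(), pd = pd_parameters(),
                             demo = demographics_simulation(), seed = 1,
                             shared_eta = TRUE, grid_step = 0.25, dt = 0.025) {
  subjects0 <- sample_population(n, demo, seed = seed)
  subjects0 <- draw_random_effects(subjects0, pk, pd, seed = seed + 1L)
  out <- lapply(seq_along(regimens), function(j) {
    reg <- regimens[[j]]
    subjects <- if (shared_eta) subjects0 else
      draw_random_effects(sample_population(n, demo, seed = seed + 10L * j),
                          pk, pd, seed = seed + 10L * j + 1L)
    cur <- .population_curves(subjects, reg, pk, pd, grid_step, dt)
    ndays <- reg$horizon / 24
    metr <- do.call(rbind, lapply(seq_len(n), function(i)
      cbind(ID = i, regimen_metrics(cur$time, cur$ph[i, ]))))
    daycmax <- do.call(rbind, lapply(seq_len(ndays), function(d) {
      sel <- cur$time >= 24 * (d - 1) & cur$time <= 24 * d
      tibble::tibble(window = paste0("day", d),
                     median_day_cmax = median(apply(cur$cp[, sel, drop = FALSE], 1, max)))
    }))
    med <- do.call(rbind, lapply(split(metr, metr$window), function(m)
      tibble::tibble(regimen = names(regimens)[j], window = m$window[1L],
                     median_mean_ph = median(m$mean_ph),
                     median_pct_above4 = median(m$pct_above4),
                     median_pct_above6 = median(m$pct_above6))))
    med <- merge(med, daycmax, by = "window")
    overall_mean <- vapply(seq_len(n), function(i)
      .trapz_mean(cur$time, cur$ph[i, ], 0, reg$horizon), numeric(1))
    list(summary = tibble::as_tibble(med),
         overall = tibble::tibble(regimen = names(regimens)[j],
                                  label = reg$label,
                                  median_mean_ph_overall = median(overall_mean)),
         bands = cbind(regimen = names(regimens)[j], .bands(cur$time, cur$ph)))
  })
  list(summary = do.call(rbind, lapply(out, `[[`, "summary")),
       overall = do.call(rbind, lapply(out, `[[`, "overall")),
       bands = do.call(rbind, lapply(out, `[[`, "bands")))
}
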