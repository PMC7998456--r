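## Extract the replication design of a dataset: subjects with covariates,
## per-occasion dose events and nominal observation schedules.
.dataset_design <- function(ds) {
  subs <- .split_dataset(ds)
  lapply(subs, function(s) {
    list(ID = s$ID, WT = s$WT, SEX = s$SEX,
         occs = lapply(s$occs, function(o)
           list(doses = o$doses, conc_t = o$conc$TIME, ph_t = o$ph$TIME)))
  })
}

## Simulate one replicate of a design under (pk, pd); returns vectors of
## simulated DV aligned with the observed record order of .vpc_obs().
.simulate_design <- function(design, pk, pd, with_noise = TRUE, dt = 0.025) {
  out <- vector("list", length(design))
  for (i in seq_along(design)) {
    s <- design[[i]]
    eta_pk <- .draw_eta(pk$omega)
    eta_pd <- if (!is.null(pd)) .draw_eta(pd$omega) else numeric(3)
    pk_i <- individual_parameters(pk, s$WT, s$SEX, eta_pk)
    occ <- vector("list", length(s$occs))
    for (k in seq_along(s$occs)) {
      o <- s$occs[[k]]
      cp <- ph <- numeric(0)
      if (length(o$conc_t)) {
        cp <- pk_concentration(o$conc_t, o$doses, pk_i)
        if (with_noise) cp <- cp * (1 + rnorm(length(cp), 0, pk$sigma_prop))
      }
      if (length(o$ph_t) && !is.null(pd)) {
        reg <- regimen(o$doses, label = "rep",
                       horizon = max(o$ph_t, o$doses$start_time +
                                       o$doses$duration))
        sim <- simulate_individual(reg, pk_i, pd, grid = o$ph_t,
                                   eta_pd = eta_pd, dt = dt)
        ph <- sim$pH
        if (with_noise) ph <- ph + rnorm(length(ph), 0, pd$sigma_add)
      }
      occ[[k]] <- list(cp = cp, ph = ph)
    }
    out[[i]] <- occ
  }
  out
}

.vpc_obs <- function(ds) {
  r <- ds$records
  obs <- r[r$MDV == 0 & r$DVTYPE %in% c(1, 2), ]
  obs[order(match(obs$ID, unique(r$ID)), obs$OCC, obs$DVTYPE, obs$TIME), ]
}

#' Visual predictive check
#'
#' Simulates `n_rep` full-design replicates of the dataset from the supplied
#' population parameters (random effects and residual error redrawn each
#' replicate), bins observations and simulations by nominal sampling time
#' within occasion and record type, and compares observed percentiles with
#' the simulation percentile bands. The coverage statistic is the fraction
#' of observed records inside the simulated 5th-95th band (nominally 90%
#' under the true model).
#'
#' @param dataset a [study_dataset()]
#' @param pk a [pk_parameters()]
#' @param pd a [pd_parameters()] (may be `NULL` for concentration-only VPC)
#' @param n_rep number of simulation replicates
#' @param seed seed
#' @param dt PD integration step (h)
#' @return A `vpc_result`: `bins` (per OCC/DVTYPE/TIME observed and
#'   simulated percentiles with 95% envelopes over replicates), `coverage`
#'   (per DVTYPE and overall), `n_rep`.
#' @export
vpc <- function(dataset, pk = pk_parameters(), pd = pd_parameters(),
                n_rep = 500, seed = 1, dt = 0.025) {
  stopifnot(n_rep >= 1)
  design <- .dataset_design(dataset)
  obs <- .vpc_obs(dataset)
  if (!nrow(obs)) stop("dataset has no observations", call. = FALSE)
  sims <- matrix(NA_real_, nrow(obs), n_rep)
  .with_seed(seed, {
    for (r in seq_len(n_rep)) {
      rep <- .simulate_design(design, pk, pd, with_noise = TRUE, dt = dt)
      v <- unlist(lapply(seq_along(design), function(i)
        unlist(lapply(seq_along(design[[i]]$occs), function(k)
          c(rep[[i]][[k]]$cp, rep[[i]][[k]]$ph)), use.names = FALSE)),
        use.names = FALSE)
      ## alignment: .simulate_design emits conc then pH per occasion in
      ## nominal time order, matching the .vpc_obs() record order
      sims[, r] <- v
    }
  })
  bin_id <- paste(obs$OCC, obs$DVTYPE, obs$TIME)
  lo <- apply(sims, 1, quantile, 0.05, names = FALSE)
  hi <- apply(sims, 1, quantile, 0.95, names = FALSE)
  inside <- obs$DV >= lo & obs$DV <= hi
  bins <- lapply(split(seq_len(nrow(obs)), bin_id), function(ix) {
    sm <- sims[ix, , drop = FALSE]
    rep_q <- apply(sm, 2, quantile, probs = c(0.05, 0.5, 0.95),
                   names = FALSE)
    if (is.null(dim(rep_q))) rep_q <- matrix(rep_q, 3)
    env <- apply(rep_q, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
    tibble::tibble(
      OCC = obs$OCC[ix][1L], DVTYPE = obs$DVTYPE[ix][1L],
      TIME = obs$TIME[ix][1L], n_obs = length(ix),
      obs_p5 = quantile(obs$DV[ix], 0.05, names = FALSE),
      obs_p50 = median(obs$DV[ix]),
      obs_p95 = quantile(obs$DV[ix], 0.95, names = FALSE),
      sim_p5 = quantile(sm, 0.05), sim_p50 = quantile(sm, 0.5),
      sim_p95 = quantile(sm, 0.95),
      env_p50_lo = env[1, 2], env_p50_hi = env[2, 2])
  })
  bins <- do.call(rbind, bins)
  bins <- bins[order(bins$DVTYPE, bins$OCC, bins$TIME), ]
  cov_by <- vapply(split(inside, obs$DVTYPE), mean, numeric(1))
  structure(list(bins = bins,
                 coverage = list(by_type = cov_by, overall = mean(inside)),
                 n_rep = n_rep),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d replicates, %d bins\n", x$n_rep, nrow(x$bins)))
  cat(sprintf("  coverage of simulated 5-95%% band: overall %.1f%%\n",
              100 * x$coverage$overall))
  for (ty in names(x$coverage$by_type))
    cat(sprintf("    DVTYPE %s: %.1f%%\n", ty,
                100 * x$coverage$by_type[[ty]]))
  invisible(x)
}

#' Goodness-of-fit tables
#'
#' Population predictions (eta = 0), individual predictions (empirical
#' Bayes etas from the fit), residuals, individually weighted residuals and
#' first-order weighted residuals (residuals scaled by the model-implied SD
#' including the linearized BSV contribution) per record, with bias/spread
#' summaries.
#'
#' @param dataset the fitted dataset
#' @param fit a `fit_result` from [fit_pk()] or [fit_pd_sequential()]
#' @param pk_individual individual PK table (PD-stage fits only)
#' @return List with `table` (per-record tibble: `ID`, `OCC`, `TIME`,
#'   `DVTYPE`, `DV`, `PRED`, `IPRED`, `RES`, `IRES`, `IWRES`, `WRES`) and
#'   `summary` (mean and SD of the weighted residuals).
#' @export
gof <- function(dataset, fit, pk_individual = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  spec <- fit$spec
  model <- if (fit$stage == "pk") {
    .build_pk_model(dataset, spec, NULL)
  } else {
    .build_pd_model(dataset, pk_individual, spec, NULL)
  }
  th <- fit$estimates
  omega <- model$omega(th)
  sigma <- model$sigma(th)
  prop <- identical(model$error, "prop")
  et <- fit$etas
  rows <- lapply(model$subjects, function(s) {
    q <- length(omega)
    eta_hat <- if (!is.null(et) && s$ID %in% et$ID) {
      unlist(et[match(s$ID, et$ID), paste0("eta_", names(omega))])
    } else numeric(q)
    f0 <- model$pred(s, th, numeric(q))
    fi <- model$pred(s, th, eta_hat)
    ## linearized variance of y around eta = 0 for the weighted residual
    G <- matrix(0, length(f0), q)
    h <- 1e-4
    for (k in seq_len(q)) {
      ep <- numeric(q); ep[k] <- h
      G[, k] <- (model$pred(s, th, ep) - model$pred(s, th, -ep)) / (2 * h)
    }
    vres <- if (prop) sigma^2 * f0^2 else rep.int(sigma^2, length(f0))
    vtot <- vres + rowSums((G %*% diag(omega^2, q)) * G)
    occ_ix <- rep(seq_along(s$occs),
                  vapply(s$occs, function(o)
                    length(o$y %||% o$conc$DV %||% 0), 0L))
    tibble::tibble(ID = s$ID, OCC = occ_ix,
                   TIME = unlist(lapply(s$occs, function(o)
                     o$obs_t %||% o$conc$TIME)),
                   DVTYPE = if (fit$stage == "pk") 1L else 2L,
                   DV = s$y, PRED = f0, IPRED = fi,
                   RES = s$y - f0, IRES = s$y - fi,
                   IWRES = (s$y - fi) /
                     (if (prop) sigma * pmax(fi, 1e-12) else sigma),
                   WRES = (s$y - f0) / sqrt(vtot))
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = tibble::tibble(
         mean_wres = mean(tab$WRES), sd_wres = sd(tab$WRES),
         mean_iwres = mean(tab$IWRES), sd_iwres = sd(tab$IWRES),
         rmse_pred = sqrt(mean(tab$RES^2)),
         rmse_ipred = sqrt(mean(tab$IRES^2))))
}

#' External validation against an independent study
#'
#' Simulates prediction bands (5th/50th/95th percentiles over `n_rep`
#' replicates) at the design of an external dataset that was not used for
#' fitting, flags each observed record as inside or outside the band, and
#' reports coverage by record type.
#'
#' @param dataset_external a [study_dataset()] from an independent design
#' @param pk,pd population parameters (from the internal fit)
#' @param n_rep number of replicates
#' @param seed seed
#' @param dt PD integration step (h)
#' @return List with `records` (observed records plus `sim_p5`, `sim_p50`,
#'   `sim_p95`, `inside`), `coverage` (per DVTYPE and overall) and `n_rep`.
#' @export
external_validation <- function(dataset_external, pk = pk_parameters(),
                                pd = pd_parameters(), n_rep = 200, seed = 1,
                                dt = 0.025) {
  obs <- .vpc_obs(dataset_external)
  if (!nrow(obs))
    stop("external dataset contains no observations", call. = FALSE)
  v <- vpc(dataset_external, pk, pd, n_rep = n_rep, seed = seed, dt = dt)
  key <- paste(obs$OCC, obs$DVTYPE, obs$TIME)
  bin <- match(key, paste(v$bins$OCC, v$bins$DVTYPE, v$bins$TIME))
  rec <- tibble::tibble(obs,
                        sim_p5 = v$bins$sim_p5[bin],
                        sim_p50 = v$bins$sim_p50[bin],
                        sim_p95 = v$bins$sim_p95[bin])
  rec$inside <- rec$DV >= rec$sim_p5 & rec$DV <= rec$sim_p95
  list(records = rec,
       coverage = list(
         by_type = vapply(split(rec$inside, rec$DVTYPE), mean, numeric(1)),
         overall = mean(rec$inside)),
       n_rep = n_rep)
}
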