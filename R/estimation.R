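#' Structural and covariate specification of the population PK model
#'
#' Candidate structures for model selection: one- or two-compartment
#' disposition with linear or Michaelis-Menten (saturable) elimination,
#' optional covariates (allometric body weight on `Vc`, sex on `CLp`), and a
#' configurable set of parameters carrying between-subject variability.
#' The reference model is the two-compartment linear model with both
#' covariates and BSV on all four disposition parameters.
#'
#' @param n_compartments 1 or 2
#' @param elimination `"linear"` or `"mm"` (Michaelis-Menten; parameters
#'   `Vm` mg/h and `Km` mg/L replace `CLp`)
#' @param covariate_wt include the weight covariate on `Vc`
#' @param covariate_sex include the sex covariate on `CLp` (linear
#'   elimination only)
#' @param bsv character vector of structural parameters with random effects;
#'   `NULL` = all disposition parameters except `Km`
#' @return A `pk_model_spec`.
#' @export
pk_model_spec <- function(n_compartments = 2,
                          elimination = c("linear", "mm"),
                          covariate_wt = TRUE, covariate_sex = TRUE,
                          bsv = NULL) {
  elimination <- match.arg(elimination)
  stopifnot(n_compartments %in% c(1, 2))
  structural <- c(if (elimination == "linear") "CLp" else c("Vm", "Km"),
                  if (n_compartments == 2) "CLt", "Vc",
                  if (n_compartments == 2) "Vt")
  if (elimination == "mm") covariate_sex <- FALSE
  if (is.null(bsv)) bsv <- setdiff(structural, "Km")
  if (!all(bsv %in% structural))
    stop("bsv names must be structural parameters: ",
         paste(structural, collapse = ", "), call. = FALSE)
  structure(list(n_compartments = n_compartments, elimination = elimination,
                 covariate_wt = covariate_wt, covariate_sex = covariate_sex,
                 structural = structural, bsv = bsv),
            class = "pk_model_spec")
}

#' Specification of the sequential gastric-acid PD fit
#'
#' The sequential stage conditions on individual PK parameters and estimates
#' the pump-turnover system: `kdeg`, `kd`, `kout` with log-normal BSV, the
#' meal parameters `FE4h`, `FE10h`, `kFE` as population-typical values, and
#' the additive pH residual SD. `HBASE` is fixed (as in the reference
#' analysis) and the circadian surge parameters are fixed by default (they
#' are identified from mean drug-free baseline behaviour and do not converge
#' with BSV switched on).
#'
#' @param estimate fixed-effect parameters to estimate
#' @param bsv parameters carrying BSV (subset of `kdeg`, `kd`, `kout`)
#' @param estimate_circadian also estimate `MA`, `MW`, `MTmax`
#' @param dt PD integration step used during estimation (h)
#' @param dose_clock clock time of the simulation origin (h)
#' @return A `pd_model_spec`.
#' @export
pd_model_spec <- function(estimate = c("kdeg", "kd", "kout", "FE4h", "FE10h",
                                       "kFE"),
                          bsv = c("kdeg", "kd", "kout"),
                          estimate_circadian = FALSE,
                          dt = 0.025, dose_clock = 8) {
  if (!all(bsv %in% c("kdeg", "kd", "kout")))
    stop("PD BSV is supported on kdeg, kd, kout", call. = FALSE)
  if (estimate_circadian) estimate <- union(estimate, c("MA", "MW", "MTmax"))
  structure(list(estimate = estimate, bsv = bsv,
                 estimate_circadian = estimate_circadian,
                 dt = dt, dose_clock = dose_clock),
            class = "pd_model_spec")
}

## ---------------------------------------------------------------------------
## parameter packing: each outer parameter has a name, a transformation scale
## ("log" for positive parameters, mu-referencing style; "identity"), a start
## and an estimated flag
.par_spec <- function(name, scale, start, est) {
  data.frame(name = name, scale = scale, start = as.numeric(start), est = est,
             stringsAsFactors = FALSE)
}

.pack <- function(ps) {
  v <- ifelse(ps$scale == "log", log(ps$start), ps$start)
  setNames(v[ps$est], ps$name[ps$est])
}

.unpack <- function(ps, v) {
  full <- ifelse(ps$scale == "log", log(ps$start), ps$start)
  full[ps$est] <- v
  out <- ifelse(ps$scale == "log", exp(full), full)
  setNames(as.list(out), ps$name)
}

## Box constraints on the transformed scale: log parameters stay within a
## factor e^4 of their starting values (keeps line searches away from
## overflow/underflow regions), identity parameters within +/- 4.
.par_bounds <- function(ps) {
  ctr <- ifelse(ps$scale == "log", log(ps$start), ps$start)[ps$est]
  list(lower = ctr - 4, upper = ctr + 4)
}

## ---------------------------------------------------------------------------
## inner problem: per-subject joint -2 log posterior over eta
##   g(eta) = sum_j [ log(2 pi v_j) + (y_j - f_j)^2 / v_j ]
##            + q log(2 pi) + log|Omega| + eta' Omega^-1 eta
## minimized by a damped Gauss-Newton iteration with finite-difference
## prediction Jacobians; the GN curvature doubles as the FOCE-I Laplace
## Hessian. Warm starts across outer iterations keep the cost at a few
## model evaluations per subject.
.inner_g <- function(f, y, eta, sigma2, prop, Oinv, logdetO) {
  if (!all(is.finite(f))) return(list(g = 1e10, ok = FALSE))
  if (prop && any(f <= 0)) return(list(g = 1e10, ok = FALSE))
  v <- if (prop) sigma2 * f * f else rep.int(sigma2, length(f))
  e <- y - f
  g <- sum(log(2 * pi * v) + e * e / v) + length(eta) * log(2 * pi) +
    logdetO + sum(eta * (Oinv %*% eta))
  list(g = g, v = v, e = e, ok = is.finite(g))
}

.inner_grad <- function(pred, f, cur, eta, prop, Oinv, h) {
  q <- length(eta)
  if (q == 0L) return(numeric(0))
  J <- matrix(0, length(f), q)
  for (k in seq_len(q)) {
    ep <- eta; ep[k] <- ep[k] + h
    em <- eta; em[k] <- em[k] - h
    J[, k] <- (pred(ep) - pred(em)) / (2 * h)
  }
  w <- if (prop) {
    2 / f - 2 * cur$e / cur$v - 2 * cur$e^2 / (cur$v * f)
  } else -2 * cur$e / cur$v
  drop(crossprod(J, w)) + 2 * drop(Oinv %*% eta)
}

.inner_solve <- function(pred, y, q, sigma2, prop, Oinv, logdetO,
                         eta0 = numeric(q), maxit = 40L, tol = 1e-7) {
  eta <- eta0
  f <- pred(eta)
  cur <- .inner_g(f, y, eta, sigma2, prop, Oinv, logdetO)
  if (!cur$ok) { eta <- numeric(q); f <- pred(eta)
                 cur <- .inner_g(f, y, eta, sigma2, prop, Oinv, logdetO) }
  if (!cur$ok) stop("inner objective not finite at eta = 0")
  h <- 1e-4
  lam <- 1e-8
  J <- matrix(0, length(y), q)
  done <- FALSE
  for (it in seq_len(maxit)) {
    if (length(y) == 0L || q == 0L || done) break
    for (k in seq_len(q)) {
      ep <- eta; ep[k] <- ep[k] + h
      em <- eta; em[k] <- em[k] - h
      J[, k] <- (pred(ep) - pred(em)) / (2 * h)
    }
    if (!all(is.finite(J))) break
    w <- if (prop) {
      2 / f - 2 * cur$e / cur$v - 2 * cur$e^2 / (cur$v * f)
    } else -2 * cur$e / cur$v
    grad <- drop(crossprod(J, w)) + 2 * drop(Oinv %*% eta)
    if (!all(is.finite(grad)) || max(abs(grad)) < 1e-7) break
    H <- 2 * crossprod(J, J / cur$v) + 2 * Oinv
    accepted <- FALSE
    for (try in 1:6) {
      delta <- tryCatch(-solve(H + lam * diag(q), grad),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        step <- 1
        for (bt in 1:6) {  # backtracking line search along the GN direction
          eta_new <- eta + step * delta
          f_new <- pred(eta_new)
          new <- .inner_g(f_new, y, eta_new, sigma2, prop, Oinv, logdetO)
          if (new$ok && new$g <= cur$g + 1e-12) {
            accepted <- TRUE
            if (max(abs(step * delta)) < tol) done <- TRUE
            eta <- eta_new; f <- f_new; cur <- new
            lam <- max(lam * 0.3, 1e-10)
            break
          }
          step <- step / 4
        }
        if (accepted) break
      }
      lam <- lam * 30
    }
    if (!accepted) break
  }
  ## quasi-Newton fallback when the GN iteration stalls away from a stationary
  ## point (strongly nonlinear subjects with large etas)
  if (q > 0L && length(y) > 0L) {
    gfun <- function(e) .inner_g(pred(e), y, e, sigma2, prop, Oinv, logdetO)$g
    gr <- .inner_grad(pred, f, cur, eta, prop, Oinv, h)
    if (!all(is.finite(gr))) gr <- Inf
    if (!done && max(abs(gr)) > 1e-4 * (1 + abs(cur$g))) {
      for (e0 in list(eta, numeric(q))) {
        alt <- tryCatch(nlminb(e0, gfun, control = list(rel.tol = 1e-12)),
                        error = function(e) NULL)
        if (!is.null(alt) && is.finite(alt$objective) &&
            alt$objective < cur$g) {
          eta <- alt$par
          f <- pred(eta)
          cur <- .inner_g(f, y, eta, sigma2, prop, Oinv, logdetO)
        }
      }
    }
  }
  ## final curvature at the mode
  if (q > 0L && length(y) > 0L) {
    for (k in seq_len(q)) {
      ep <- eta; ep[k] <- ep[k] + h
      em <- eta; em[k] <- em[k] - h
      J[, k] <- (pred(ep) - pred(em)) / (2 * h)
    }
    H <- 2 * crossprod(J, J / cur$v) + 2 * Oinv
  } else {
    H <- 2 * Oinv
  }
  list(eta = eta, g = cur$g, f = f, J = J, v = cur$v, H = H)
}

## Laplace/FOCE-I marginal contribution of one subject.
.subject_ofv <- function(model, th, subj, sigma2, prop, Oinv, logdetO, q,
                         eta0, method) {
  pred <- function(eta) model$pred(subj, th, eta)
  if (q == 0L) {
    f <- pred(numeric(0))
    gg <- .inner_g(f, subj$y, numeric(0), sigma2, prop, Oinv, logdetO)
    return(list(ofv = gg$g, eta = numeric(0)))
  }
  sol <- .inner_solve(pred, subj$y, q, sigma2, prop, Oinv, logdetO, eta0)
  H <- sol$H
  if (identical(method, "laplace") && length(subj$y) > 0L) {
    gfun <- function(eta)
      .inner_g(pred(eta), subj$y, eta, sigma2, prop, Oinv, logdetO)$g
    Hfd <- tryCatch(optimHess(sol$eta, gfun), error = function(e) NULL)
    if (!is.null(Hfd)) {
      ok <- tryCatch({ chol(Hfd / 2); TRUE }, error = function(e) FALSE)
      if (ok) H <- Hfd
    }
  }
  ld <- 2 * sum(log(diag(chol(H / 2))))
  list(ofv = sol$g - q * log(2 * pi) + ld, eta = sol$eta)
}

## Full marginal -2 log-likelihood over subjects; eta warm starts kept in
## `cache` (an environment) across outer iterations. A compiled batch path
## handles all subjects in one call; subjects whose inner problem does not
## converge there are retried on the slower, more forgiving R path (damped
## GN plus quasi-Newton fallback).
.foce_ofv <- function(model, th, cache = NULL, method = "foce",
                      keep = FALSE) {
  omega <- model$omega(th)
  sigma <- model$sigma(th)
  if (!is.finite(sigma) || sigma <= 0) return(list(ofv = 1e10))
  active <- omega > 1e-8
  q <- sum(active)
  Oinv <- if (q) diag(1 / omega[active]^2, q) else matrix(0, 0, 0)
  logdetO <- if (q) sum(2 * log(omega[active])) else 0
  prop <- identical(model$error, "prop")
  sigma2 <- sigma^2
  S <- length(model$subjects)
  eta0m <- matrix(0, S, q)
  if (!is.null(cache) && !is.null(cache$etas) &&
      identical(dim(cache$etas), dim(eta0m))) eta0m <- cache$etas
  total <- 0
  etas <- matrix(0, S, length(omega))
  slow_idx <- seq_len(S)
  if (!is.null(model$fast) && q > 0) {
    fr <- tryCatch(model$fast(th, omega[active], which(active), sigma, eta0m,
                              identical(method, "laplace")),
                   error = function(e) NULL)
    if (!is.null(fr)) {
      okv <- fr$ok
      total <- sum(fr$ofv[okv])
      etas[okv, active] <- fr$etas[okv, , drop = FALSE]
      slow_idx <- which(!okv)
    }
  }
  for (i in slow_idx) {
    subj <- model$subjects[[i]]
    ## expand active-eta vector to the full eta layout expected by pred
    full_pred_model <- list(pred = function(s, t, e_act) {
      e <- numeric(length(omega)); e[active] <- e_act
      model$pred(s, t, e)
    })
    res <- tryCatch(
      .subject_ofv(full_pred_model, th, subj, sigma2, prop, Oinv, logdetO,
                   q, eta0m[i, ], method),
      error = function(e) {
        warning("subject ", subj$ID, ": ", conditionMessage(e),
                "; contribution penalized", call. = FALSE)
        list(ofv = 1e7, eta = numeric(q))
      })
    total <- total + res$ofv
    if (q) etas[i, active] <- res$eta
  }
  if (!is.null(cache)) cache$etas <- etas[, active, drop = FALSE]
  out <- list(ofv = total)
  if (keep) {
    out$etas <- tibble::tibble(
      ID = unname(vapply(model$subjects, `[[`, 0, "ID")))
    for (j in seq_along(omega))
      out$etas[[paste0("eta_", names(omega)[j])]] <- as.numeric(etas[, j])
  }
  out
}

## ---------------------------------------------------------------------------
## PK model construction

.pk_conc_1cmt <- function(t, doses, CL, V) {
  k <- CL / V
  out <- numeric(length(t))
  for (i in seq_len(nrow(doses))) {
    if (doses$amount[i] <= 0) next
    te <- t - doses$start_time[i]
    rate <- doses$amount[i] / doses$duration[i]
    pos <- te > 0
    if (!any(pos)) next
    tp <- te[pos]
    out[pos] <- out[pos] + (rate / CL) *
      (exp(-k * pmax(0, tp - doses$duration[i])) - exp(-k * tp))
  }
  1000 * out
}

.pk_conc_mm <- function(t, doses, Vm, Km, CLt, Vc, Vt, two_cmt) {
  rate_fn <- function(tt) {
    r <- 0
    for (i in seq_len(nrow(doses))) {
      if (tt > doses$start_time[i] &&
          tt <= doses$start_time[i] + doses$duration[i])
        r <- r + doses$amount[i] / doses$duration[i]
    }
    r
  }
  rhs <- function(tt, y, p) {
    C1 <- y[1] / Vc
    el <- Vm * C1 / (Km + C1)
    if (two_cmt) {
      C2 <- y[2] / Vt
      list(c(rate_fn(tt) - el - CLt * (C1 - C2), CLt * (C1 - C2)))
    } else list(rate_fn(tt) - el)
  }
  y0 <- if (two_cmt) c(0, 0) else 0
  tt <- sort(unique(c(0, t, doses$start_time,
                      doses$start_time + doses$duration)))
  sol <- deSolve::lsoda(y0, tt, rhs, NULL, rtol = 1e-8, atol = 1e-10,
                        hmax = 0.25)
  1000 * sol[match(t, tt), 2] / Vc
}

.build_pk_model <- function(ds, spec, init) {
  subs <- .split_dataset(ds)
  subjects <- lapply(subs, function(s) {
    occ <- Filter(function(o) nrow(o$conc) > 0, s$occs)
    occs <- lapply(occ, function(o)
      list(tt = as.numeric(o$conc$TIME),
           d_start = as.numeric(o$doses$start_time),
           d_amt = as.numeric(o$doses$amount),
           d_dur = as.numeric(o$doses$duration),
           doses = o$doses, conc = o$conc))
    ## flattened all-occasion layout for single-call C++ evaluation
    list(ID = s$ID, WT = s$WT, SEX = s$SEX, occs = occs,
         t_all = unlist(lapply(occs, `[[`, "tt"), use.names = FALSE),
         tgrp = rep(seq_along(occs),
                    vapply(occs, function(o) length(o$tt), 0L)),
         ds_all = unlist(lapply(occs, `[[`, "d_start"), use.names = FALSE),
         da_all = unlist(lapply(occs, `[[`, "d_amt"), use.names = FALSE),
         dd_all = unlist(lapply(occs, `[[`, "d_dur"), use.names = FALSE),
         dgrp = rep(seq_along(occs),
                    vapply(occs, function(o) length(o$d_start), 0L)),
         y = as.numeric(unlist(lapply(occ, function(o) o$conc$DV))))
  })
  subjects <- Filter(function(s) length(s$y) > 0, subjects)
  if (!length(subjects))
    stop("dataset contains no concentration observations", call. = FALSE)
  bsv <- spec$bsv
  two <- spec$n_compartments == 2
  mm <- spec$elimination == "mm"
  iCLp <- match("CLp", bsv); iCLt <- match("CLt", bsv)
  iVc <- match("Vc", bsv); iVt <- match("Vt", bsv)
  iVm <- match("Vm", bsv)
  cov_wt <- spec$covariate_wt; cov_sex <- spec$covariate_sex
  ex <- function(eta, i) if (is.na(i)) 1 else exp(eta[i])
  pred <- function(subj, th, eta) {
    Vc_i <- th$Vc * ex(eta, iVc) *
      (if (cov_wt) (subj$WT / 70)^th$theta_wt else 1)
    nocc <- length(subj$occs)
    out <- vector("list", nocc)
    if (!mm) {
      CLp_i <- th$CLp * ex(eta, iCLp) *
        (if (cov_sex) th$theta_sex^subj$SEX else 1)
      if (two) {
        return(pk_conc2_multi_cpp(subj$t_all, subj$tgrp, subj$ds_all,
                                  subj$da_all, subj$dd_all, subj$dgrp,
                                  CLp_i, th$CLt * ex(eta, iCLt), Vc_i,
                                  th$Vt * ex(eta, iVt)))
      } else {
        for (k in seq_len(nocc)) {
          o <- subj$occs[[k]]
          out[[k]] <- .pk_conc_1cmt(o$tt, o$doses, CLp_i, Vc_i)
        }
      }
    } else {
      for (k in seq_len(nocc)) {
        o <- subj$occs[[k]]
        out[[k]] <- .pk_conc_mm(o$tt, o$doses, th$Vm * ex(eta, iVm), th$Km,
                                if (two) th$CLt * ex(eta, iCLt) else 0, Vc_i,
                                if (two) th$Vt * ex(eta, iVt) else 1, two)
      }
    }
    if (nocc == 1L) out[[1L]] else unlist(out, use.names = FALSE)
  }
  start <- .pk_naive_init(subjects, spec)
  if (!is.null(init)) start <- modifyList(start, .init_as_list(init, spec))
  nm <- c(spec$structural,
          if (spec$covariate_wt) "theta_wt",
          if (spec$covariate_sex) "theta_sex",
          paste0("om_", bsv), "sigma_prop")
  sc <- ifelse(nm == "theta_wt", "identity", "log")
  st <- vapply(nm, function(p) start[[p]] %||% 0.3, numeric(1))
  ps <- .par_spec(nm, sc, st, rep(TRUE, length(nm)))
  ## batched compiled inner path (2-compartment linear models only)
  fast <- NULL
  if (two && !mm) {
    nobs <- vapply(subjects, function(s) length(s$y), 0L)
    ndose <- vapply(subjects, function(s) length(s$ds_all), 0L)
    fd <- list(
      t = unlist(lapply(subjects, `[[`, "t_all"), use.names = FALSE),
      tgrp = unlist(lapply(subjects, `[[`, "tgrp"), use.names = FALSE),
      y = unlist(lapply(subjects, `[[`, "y"), use.names = FALSE),
      obs_off = c(0L, cumsum(nobs)),
      ds = unlist(lapply(subjects, `[[`, "ds_all"), use.names = FALSE),
      da = unlist(lapply(subjects, `[[`, "da_all"), use.names = FALSE),
      dd = unlist(lapply(subjects, `[[`, "dd_all"), use.names = FALSE),
      dgrp = unlist(lapply(subjects, `[[`, "dgrp"), use.names = FALSE),
      dose_off = c(0L, cumsum(ndose)),
      WT = vapply(subjects, `[[`, 0, "WT"),
      SEX = vapply(subjects, `[[`, 0, "SEX"),
      bsv_idx = match(bsv, c("CLp", "CLt", "Vc", "Vt")) - 1L)
    Sn <- length(subjects)
    fast <- function(th, omega_act, act, sigma, eta0, exact = FALSE) {
      CLp_b <- rep.int(th$CLp, Sn) *
        (if (cov_sex) th$theta_sex^fd$SEX else 1)
      Vc_b <- rep.int(th$Vc, Sn) *
        (if (cov_wt) (fd$WT / 70)^th$theta_wt else 1)
      foce_pk_batch_cpp(fd$t, fd$tgrp, fd$y, fd$obs_off, fd$ds, fd$da,
                        fd$dd, fd$dgrp, fd$dose_off, CLp_b,
                        rep.int(th$CLt, Sn), Vc_b, rep.int(th$Vt, Sn),
                        fd$bsv_idx[act], omega_act, sigma, eta0, 40L,
                        exact)
    }
  }
  list(kind = "pk", subjects = subjects, error = "prop", spec = spec,
       par_spec = ps, bsv = bsv, fast = fast,
       pred = pred,
       omega = function(th) setNames(
         vapply(bsv, function(p) th[[paste0("om_", p)]], 0), bsv),
       sigma = function(th) th$sigma_prop,
       data_key = c(n = sum(vapply(subjects, function(s) length(s$y), 0L)),
                    s = sum(unlist(lapply(subjects, `[[`, "y")))))
}

## Naive pooled starting values: per subject-occasion trapezoidal AUC and
## Cmax give clearance and central-volume scale estimates.
.pk_naive_init <- function(subjects, spec) {
  cl <- vc <- numeric(0)
  for (s in subjects) for (o in s$occs) {
    dose <- sum(o$doses$amount)
    tt <- o$conc$TIME; dv <- o$conc$DV
    if (dose <= 0 || length(tt) < 3) next
    auc <- sum(diff(tt) * (head(dv, -1) + tail(dv, -1)) / 2) / 1000  # mg*h/L
    if (auc > 0) cl <- c(cl, dose / auc)
    cmax <- max(dv) / 1000
    if (cmax > 0) vc <- c(vc, dose / cmax)
  }
  CL <- if (length(cl)) median(cl) else 3
  VC <- if (length(vc)) median(vc) else 10
  out <- list(CLp = CL, CLt = CL, Vc = VC, Vt = VC / 2,
              Vm = 3 * CL, Km = 3,
              theta_wt = 1, theta_sex = 1, sigma_prop = 0.2)
  for (p in spec$bsv) out[[paste0("om_", p)]] <- 0.3
  out
}

.init_as_list <- function(init, spec) {
  if (inherits(init, "pk_parameters")) {
    out <- list(CLp = init$CLp, CLt = init$CLt, Vc = init$Vc, Vt = init$Vt,
                theta_wt = init$theta_wt, theta_sex = init$theta_sex,
                sigma_prop = init$sigma_prop)
    for (p in names(init$omega))
      if (init$omega[[p]] > 0) out[[paste0("om_", p)]] <- init$omega[[p]]
    out
  } else if (inherits(init, "pd_parameters")) {
    out <- list(kdeg = init$kdeg, kd = init$kd, kout = init$kout,
                HBASE = init$HBASE, MA = init$MA, MW = init$MW,
                MTmax = init$MTmax, FE4h = init$FE4h, FE10h = init$FE10h,
                kFE = init$kFE, sigma_add = init$sigma_add)
    for (p in names(init$omega))
      if (init$omega[[p]] > 0) out[[paste0("om_", p)]] <- init$omega[[p]]
    out
  } else as.list(init)
}

## ---------------------------------------------------------------------------
## PD model construction (sequential stage)

.build_pd_model <- function(ds, pk_individual, spec, init) {
  subs <- .split_dataset(ds)
  pk_tab <- tibble::as_tibble(pk_individual)
  stopifnot(all(c("ID", "CLp", "CLt", "Vc", "Vt") %in% names(pk_tab)))
  dt <- spec$dt
  subjects <- lapply(subs, function(s) {
    row <- pk_tab[match(s$ID, pk_tab$ID), ]
    if (is.na(row$CLp))
      stop("no individual PK values supplied for subject ", s$ID,
           call. = FALSE)
    pk_i <- c(CLp = row$CLp, CLt = row$CLt, Vc = row$Vc, Vt = row$Vt)
    occ <- Filter(function(o) nrow(o$ph) > 0, s$occs)
    occs <- lapply(occ, function(o) {
      horizon <- max(o$ph$TIME, o$doses$start_time + o$doses$duration, 1)
      g <- .pd_grid(horizon, dt)
      pos <- o$ph$TIME / dt
      fl <- pmax(pmin(floor(pos + 1e-9), g$n - 1L), 0)
      list(doses = o$doses, obs_t = o$ph$TIME, y = o$ph$DV,
           grid = g, cp_mid = pk_concentration(g$mid, o$doses, pk_i) / 1000,
           i0 = as.integer(fl) + 1L, w = pos - fl)
    })
    list(ID = s$ID, occs = occs,
         y = unlist(lapply(occs, function(o) o$y)))
  })
  subjects <- Filter(function(s) length(s$y) > 0, subjects)
  if (!length(subjects))
    stop("dataset contains no pH observations", call. = FALSE)
  for (i in seq_along(subjects)) subjects[[i]]$pos <- i
  ## circadian factor on the step midpoints is independent of eta; cache it
  ## per subject-occasion once per outer evaluation (or permanently when the
  ## circadian parameters are fixed)
  bsv <- spec$bsv
  pred_factory <- function(th) {
    lapply(subjects, function(s) lapply(s$occs, function(o)
      .circadian(o$grid$mid + spec$dose_clock, th$MA, th$MW, th$MTmax)))
  }
  fcache <- new.env(parent = emptyenv())
  fcache$key <- NULL
  pred <- function(subj, th, eta) {
    key <- c(th$MA, th$MW, th$MTmax)
    if (is.null(fcache$key) || !identical(fcache$key, key)) {
      fcache$f <- pred_factory(th)
      fcache$key <- key
    }
    i1 <- match("kdeg", bsv); i2 <- match("kd", bsv); i3 <- match("kout", bsv)
    kdeg_i <- th$kdeg * (if (is.na(i1)) 1 else exp(eta[i1]))
    kd_i <- th$kd * (if (is.na(i2)) 1 else exp(eta[i2]))
    kout_i <- th$kout * (if (is.na(i3)) 1 else exp(eta[i3]))
    fs <- fcache$f[[subj$pos]]
    nocc <- length(subj$occs)
    out <- vector("list", nocc)
    for (k in seq_len(nocc)) {
      o <- subj$occs[[k]]
      sol <- pd_profile_cpp(o$cp_mid, fs[[k]], o$grid$dt, kdeg_i, kd_i,
                            kout_i, th$HBASE, 1, th$HBASE)
      H <- sol$H[o$i0] * (1 - o$w) + sol$H[o$i0 + 1L] * o$w
      Fe <- .food_effect(o$obs_t, th$FE4h, th$FE10h, th$kFE)
      out[[k]] <- -log10(H * Fe)
    }
    if (nocc == 1L) out[[1L]] else unlist(out, use.names = FALSE)
  }
  start <- .init_as_list(init %||% pd_parameters(), spec)
  for (p in bsv) start[[paste0("om_", p)]] <- start[[paste0("om_", p)]] %||% 0.5
  fixed_par <- c("HBASE", setdiff(c("MA", "MW", "MTmax", "FE4h", "FE10h",
                                    "kFE", "kdeg", "kd", "kout"),
                                  spec$estimate))
  nm <- c("kdeg", "kd", "kout", "HBASE", "MA", "MW", "MTmax",
          "FE4h", "FE10h", "kFE", paste0("om_", bsv), "sigma_add")
  est <- !(nm %in% fixed_par)
  ps <- .par_spec(nm, rep("log", length(nm)),
                  vapply(nm, function(p) start[[p]] %||% 0.5, 0), est)
  ## flattened occasion-level layout for the batched compiled inner path
  all_occs <- unlist(lapply(subjects, `[[`, "occs"), recursive = FALSE)
  n_grid <- vapply(all_occs, function(o) length(o$cp_mid), 0L)
  n_obs <- vapply(all_occs, function(o) length(o$y), 0L)
  fd <- list(
    cp_mid = unlist(lapply(all_occs, `[[`, "cp_mid"), use.names = FALSE),
    mid_clock = unlist(lapply(all_occs, function(o)
      o$grid$mid + spec$dose_clock), use.names = FALSE),
    grid_off = c(0L, cumsum(n_grid)),
    dtv = vapply(all_occs, function(o) o$grid$dt, 0),
    occ_off = c(0L, cumsum(vapply(subjects, function(s)
      length(s$occs), 0L))),
    y = unlist(lapply(all_occs, `[[`, "y"), use.names = FALSE),
    i0 = unlist(lapply(all_occs, function(o) o$i0 - 1L), use.names = FALSE),
    w = unlist(lapply(all_occs, `[[`, "w"), use.names = FALSE),
    tmod = unlist(lapply(all_occs, function(o) o$obs_t %% 24),
                  use.names = FALSE),
    obs_occ_off = c(0L, cumsum(n_obs)),
    bsv_idx = match(bsv, c("kdeg", "kd", "kout")) - 1L)
  fast <- function(th, omega_act, act, sigma, eta0, exact = FALSE) {
    key <- c(th$MA, th$MW, th$MTmax)
    if (is.null(fcache$fkey) || !identical(fcache$fkey, key)) {
      fcache$fall <- .circadian(fd$mid_clock, th$MA, th$MW, th$MTmax)
      fcache$fkey <- key
    }
    foce_pd_batch_cpp(fd$cp_mid, fcache$fall, fd$grid_off, fd$dtv,
                      fd$occ_off, fd$y, fd$i0, fd$w, fd$tmod,
                      fd$obs_occ_off, th$kdeg, th$kd, th$kout, th$HBASE,
                      th$FE4h, th$FE10h, th$kFE, fd$bsv_idx[act],
                      omega_act, sigma, eta0, 40L, exact)
  }
  list(kind = "pd", subjects = subjects, error = "add", spec = spec,
       par_spec = ps, bsv = bsv, pred = pred, fast = fast,
       omega = function(th) setNames(
         vapply(bsv, function(p) th[[paste0("om_", p)]], 0), bsv),
       sigma = function(th) th$sigma_add,
       data_key = c(n = sum(vapply(subjects, function(s) length(s$y), 0L)),
                    s = sum(unlist(lapply(subjects, `[[`, "y")))))
}

## ---------------------------------------------------------------------------
## outer optimization shared by both stages

.fit_outer <- function(model, method, compute_se, control, label) {
  ps <- model$par_spec
  start <- .pack(ps)
  bounds <- .par_bounds(ps)
  cache <- new.env(parent = emptyenv())
  nev <- 0L
  obj <- function(v) {
    nev <<- nev + 1L
    th <- .unpack(ps, v)
    res <- tryCatch(.foce_ofv(model, th, cache, method),
                    error = function(e) list(ofv = 1e10))
    if (!is.finite(res$ofv)) 1e10 else res$ofv
  }
  ## explicit central-difference gradient: the objective carries O(1e-6)
  ## numerical noise from the iterative inner solves, so the FD step must
  ## sit well above it
  fd_step <- control$fd_step %||% 1e-4
  forward <- identical(control$grad, "forward")
  grad <- function(v) {
    g <- numeric(length(v))
    f0 <- if (forward) obj(v) else NA_real_
    for (k in seq_along(v)) {
      vp <- v; vp[k] <- vp[k] + fd_step
      if (forward) {
        g[k] <- (obj(vp) - f0) / fd_step
      } else {
        vm <- v; vm[k] <- vm[k] - fd_step
        g[k] <- (obj(vp) - obj(vm)) / (2 * fd_step)
      }
    }
    g
  }
  ## quasi-Newton rounds with restarts: restarting resets the Hessian
  ## approximation, which helps along the long flat omega valleys typical
  ## of marginal-likelihood surfaces
  v <- start
  opt <- NULL
  iters <- 0L
  for (round in seq_len(control$restarts %||% 3L)) {
    cur <- nlminb(v, obj, gradient = grad,
                  lower = bounds$lower, upper = bounds$upper,
                  control = list(rel.tol = control$rel.tol %||% 1e-9,
                                 iter.max = control$iter.max %||% 150,
                                 eval.max = control$eval.max %||% 1000))
    iters <- iters + cur$iterations
    v <- cur$par
    improved <- is.null(opt) || opt$objective - cur$objective > 0.01
    if (is.null(opt) || cur$objective <= opt$objective) opt <- cur
    if (!improved) break
  }
  opt$iterations <- iters
  th <- .unpack(ps, opt$par)
  fin <- .foce_ofv(model, th, cache, method, keep = TRUE)
  p <- sum(ps$est)
  se <- ci <- NULL
  if (compute_se) {
    Hout <- tryCatch(optimHess(opt$par, obj), error = function(e) NULL)
    if (!is.null(Hout)) {
      cov <- tryCatch(2 * solve(Hout), error = function(e) NULL)
      if (!is.null(cov) && all(diag(cov) > 0)) {
        se_t <- sqrt(diag(cov))
        est_nm <- ps$name[ps$est]
        est_val <- vapply(est_nm, function(p) th[[p]], 0)
        islog <- ps$scale[ps$est] == "log"
        se <- ifelse(islog, est_val * se_t, se_t)
        lo <- ifelse(islog, est_val * exp(-1.96 * se_t),
                     est_val - 1.96 * se_t)
        hi <- ifelse(islog, est_val * exp(1.96 * se_t),
                     est_val + 1.96 * se_t)
        ci <- tibble::tibble(parameter = est_nm, estimate = est_val,
                             se = se, lo95 = lo, hi95 = hi)
      }
    }
  }
  structure(list(
    stage = model$kind, label = label, spec = model$spec,
    estimates = th, free = setNames(as.list(
      vapply(ps$name[ps$est], function(p) th[[p]], 0)), ps$name[ps$est]),
    ofv = fin$ofv, n_par = p, aic = fin$ofv + 2 * p,
    se_table = ci, etas = fin$etas, method = method,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations, evaluations = nev),
    data_key = model$data_key), class = "fit_result")
}

#' Approximate marginal objective (-2 log-likelihood) at given parameters
#'
#' Evaluates the FOCE-I (default) or Laplace approximation of the marginal
#' -2 log-likelihood of a dataset without optimizing. For models that are
#' linear in the random effect with Gaussian error, the approximation equals
#' the exact marginal likelihood.
#'
#' @param dataset a [study_dataset()]
#' @param spec a [pk_model_spec()] or [pd_model_spec()]
#' @param params a [pk_parameters()] (PK stage) or [pd_parameters()] (PD
#'   stage)
#' @param pk_individual individual PK values (tibble with `ID`, `CLp`,
#'   `CLt`, `Vc`, `Vt`), required for the PD stage
#' @param method `"foce"` (Gauss-Newton curvature, FOCE-I) or `"laplace"`
#'   (finite-difference Hessian)
#' @return The objective value (numeric scalar).
#' @export
marginal_objective <- function(dataset, spec, params, pk_individual = NULL,
                               method = c("foce", "laplace")) {
  method <- match.arg(method)
  model <- if (inherits(spec, "pk_model_spec")) {
    .build_pk_model(dataset, spec, params)
  } else {
    .build_pd_model(dataset, pk_individual, spec, params)
  }
  th <- .unpack(model$par_spec, .pack(model$par_spec))
  init_l <- .init_as_list(params, spec)
  for (p in intersect(names(init_l), names(th))) th[[p]] <- init_l[[p]]
  ## omegas absent from `params` mean "no random effect on this parameter"
  for (p in model$bsv)
    th[[paste0("om_", p)]] <- init_l[[paste0("om_", p)]] %||% 0
  .foce_ofv(model, th, NULL, method)$ofv
}

#' Fit the population PK model
#'
#' Maximizes the FOCE-I/Laplace marginal likelihood over the fixed effects,
#' BSV standard deviations and the proportional residual error of the
#' specified structural model. Parameters are mu-referenced (log-scale fixed
#' effects with additive etas); estimates and confidence intervals are
#' reported back-transformed to the natural scale.
#'
#' @param dataset a [study_dataset()] with concentration records
#' @param spec a [pk_model_spec()]
#' @param init optional starting values: a [pk_parameters()] or named list;
#'   defaults to naive pooled estimates (dose/AUC, dose/Cmax)
#' @param method likelihood approximation, see [marginal_objective()]
#' @param compute_se compute standard errors and 95% CIs from the curvature
#'   of the objective (adds one Hessian evaluation)
#' @param control list: `rel.tol`, `iter.max`, `eval.max`, `n_start`
#'   (multi-start count, default 1), `start_spread` (log-scale SD of
#'   multi-start perturbations, default 0.35)
#' @param seed seed for multi-start perturbations
#' @return A `fit_result` with elements `estimates` (all model parameters,
#'   natural scale), `ofv`, `aic`, `se_table`, `etas` (empirical Bayes
#'   estimates at the optimum), `convergence`.
#' @export
fit_pk <- function(dataset, spec = pk_model_spec(), init = NULL,
                   method = c("foce", "laplace"), compute_se = TRUE,
                   control = list(), seed = NULL) {
  method <- match.arg(method)
  model <- .build_pk_model(dataset, spec, init)
  .fit_multistart(model, method, compute_se, control, seed,
                  label = "population PK fit")
}

.fit_multistart <- function(model, method, compute_se, control, seed, label) {
  n_start <- control$n_start %||% 1L
  if (n_start <= 1L)
    return(.fit_outer(model, method, compute_se, control, label))
  spread <- control$start_spread %||% 0.35
  base <- model$par_spec$start
  fits <- .with_seed(seed, lapply(seq_len(n_start), function(i) {
    m <- model
    if (i > 1L) {
      fac <- exp(rnorm(length(base), 0, spread))
      m$par_spec$start <- ifelse(m$par_spec$scale == "log", base * fac, base)
    }
    tryCatch(.fit_outer(m, method, FALSE, control, label),
             error = function(e) NULL)
  }))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("all starts failed", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "ofv"))]]
  if (compute_se) {
    m <- model
    m$par_spec$start <- vapply(m$par_spec$name, function(p)
      best$estimates[[p]], 0)
    best <- .fit_outer(m, method, TRUE, control, label)
  }
  best
}

#' Empirical Bayes (post-hoc) random-effect estimates
#'
#' Maximizes each subject's joint posterior over its random effects at fixed
#' population parameters. Subjects without observations get eta = 0 (the
#' prior mode); etas shrink toward 0 as individual data vanish or omegas
#' shrink.
#'
#' @inheritParams marginal_objective
#' @return Tibble with `ID` and one `eta_*` column per BSV parameter.
#' @export
empirical_bayes <- function(dataset, spec, params, pk_individual = NULL,
                            method = c("foce", "laplace")) {
  method <- match.arg(method)
  model <- if (inherits(spec, "pk_model_spec")) {
    .build_pk_model(dataset, spec, params)
  } else {
    .build_pd_model(dataset, pk_individual, spec, params)
  }
  init_l <- .init_as_list(params, spec)
  th <- .unpack(model$par_spec, .pack(model$par_spec))
  for (p in intersect(names(init_l), names(th))) th[[p]] <- init_l[[p]]
  for (p in model$bsv)
    th[[paste0("om_", p)]] <- init_l[[paste0("om_", p)]] %||% 0
  ## subjects dropped at build (no observations) re-enter with eta = 0
  res <- .foce_ofv(model, th, NULL, method, keep = TRUE)
  all_ids <- unique(dataset$records$ID)
  out <- res$etas[match(all_ids, res$etas$ID), ]
  out$ID <- all_ids
  out[is.na(out)] <- 0
  out
}

#' Individual PK parameter table from a PK fit
#'
#' Combines the fit's fixed effects, each subject's covariates and the
#' empirical Bayes etas into individual `CLp`, `CLt`, `Vc`, `Vt` values —
#' the conditioning input of the sequential PD stage.
#'
#' @param fit a `fit_result` from [fit_pk()]
#' @param dataset the dataset the fit was obtained on
#' @return Tibble with `ID`, `WT`, `SEX`, `CLp`, `CLt`, `Vc`, `Vt`.
#' @export
pk_individual_from_fit <- function(fit, dataset) {
  stopifnot(inherits(fit, "fit_result"), fit$stage == "pk")
  th <- fit$estimates
  spec <- fit$spec
  r <- dataset$records
  cov <- unique(r[, c("ID", "WT", "SEX")])
  et <- fit$etas
  g <- function(p, id) {
    cl <- paste0("eta_", p)
    if (!is.null(et) && cl %in% names(et)) {
      v <- et[[cl]][match(id, et$ID)]
      ifelse(is.na(v), 0, v)
    } else 0
  }
  tibble::tibble(
    ID = cov$ID, WT = cov$WT, SEX = cov$SEX,
    CLp = th$CLp * exp(g("CLp", cov$ID)) *
      (if (isTRUE(spec$covariate_sex)) th$theta_sex^cov$SEX else 1),
    CLt = th$CLt * exp(g("CLt", cov$ID)),
    Vc = th$Vc * exp(g("Vc", cov$ID)) *
      (if (isTRUE(spec$covariate_wt)) (cov$WT / 70)^th$theta_wt else 1),
    Vt = th$Vt * exp(g("Vt", cov$ID)))
}

#' True individual PK parameter table from simulation random effects
#'
#' For sequential PD estimation conditioned on the *generating* individual
#' PK (an option when the PK etas are known, e.g. on synthetic data):
#' combines population parameters, covariates and supplied etas.
#'
#' @param pk a [pk_parameters()]
#' @param subjects tibble with `ID`, `WT`, `SEX` and `eta_CLp`, `eta_CLt`,
#'   `eta_Vc`, `eta_Vt` columns (see [draw_random_effects()])
#' @return Tibble with `ID`, `CLp`, `CLt`, `Vc`, `Vt`.
#' @export
pk_individual_true <- function(pk, subjects) {
  tibble::tibble(
    ID = subjects$ID,
    CLp = pk$CLp * exp(subjects$eta_CLp) * pk$theta_sex^subjects$SEX,
    CLt = pk$CLt * exp(subjects$eta_CLt),
    Vc = pk$Vc * exp(subjects$eta_Vc) * (subjects$WT / 70)^pk$theta_wt,
    Vt = pk$Vt * exp(subjects$eta_Vt))
}

#' Fit the sequential gastric-acid PD stage
#'
#' Conditional on individual PK parameter values (empirical Bayes from a PK
#' fit, or the generating values on synthetic data), estimates the pump
#' turnover/inhibition parameters with BSV, the meal-effect parameters and
#' the additive pH residual SD by FOCE-I/Laplace. `HBASE` and the circadian
#' surge parameters are fixed by default (see [pd_model_spec()]).
#'
#' @param dataset a [study_dataset()] with pH records
#' @param pk_individual tibble of individual PK values (`ID`, `CLp`, `CLt`,
#'   `Vc`, `Vt`); see [pk_individual_from_fit()] / [pk_individual_true()]
#' @param spec a [pd_model_spec()]
#' @param init starting values: a [pd_parameters()] or named list
#' @param start_perturb optional `c(lo, hi)` multiplicative range; each
#'   positive starting value is multiplied by a random factor drawn
#'   log-uniformly from this range (seeded), e.g. `c(0.5, 2)`
#' @inheritParams fit_pk
#' @return A `fit_result` (see [fit_pk()]).
#' @export
fit_pd_sequential <- function(dataset, pk_individual, spec = pd_model_spec(),
                              init = pd_parameters(), start_perturb = NULL,
                              method = c("foce", "laplace"),
                              compute_se = TRUE, control = list(),
                              seed = NULL) {
  method <- match.arg(method)
  model <- .build_pd_model(dataset, pk_individual, spec, init)
  if (!is.null(start_perturb)) {
    stopifnot(length(start_perturb) == 2, all(start_perturb > 0))
    fac <- .with_seed(seed, exp(runif(nrow(model$par_spec),
                                      log(start_perturb[1]),
                                      log(start_perturb[2]))))
    model$par_spec$start <- ifelse(model$par_spec$est,
                                   model$par_spec$start * fac,
                                   model$par_spec$start)
  }
  .fit_multistart(model, method, compute_se, control, seed,
                  label = "sequential PD fit")
}

#' Rank fitted models by AIC
#'
#' @param ... named `fit_result` objects fitted to the same dataset, or a
#'   single list of them
#' @return Tibble sorted by AIC with `ofv`, `n_par`, `aic` and `delta_aic`.
#' @export
model_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "fit_result"))
    fits <- fits[[1L]]
  stopifnot(all(vapply(fits, inherits, TRUE, "fit_result")))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  keys <- lapply(fits, `[[`, "data_key")
  if (length(unique(vapply(keys, function(k)
    paste(signif(k, 10), collapse = "|"), ""))) != 1L)
    stop("fits were not obtained on the same dataset", call. = FALSE)
  out <- tibble::tibble(
    model = names(fits),
    ofv = unname(vapply(fits, `[[`, 0, "ofv")),
    n_par = unname(vapply(fits, `[[`, 0, "n_par")),
    aic = unname(vapply(fits, `[[`, 0, "aic")))
  out <- out[order(out$aic), ]
  out$delta_aic <- out$aic - out$aic[1L]
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$label, toupper(x$method)))
  cat(sprintf("  OFV %.3f | AIC %.3f | %d parameters | convergence %d (%s)\n",
              x$ofv, x$aic, x$n_par, x$convergence$code,
              x$convergence$message %||% ""))
  if (!is.null(x$se_table)) {
    cat("  estimates (95% CI back-transformed from mu-referenced scale):\n")
    print(x$se_table, n = Inf)
  } else {
    est <- x$free
    cat("  estimates:\n")
    for (p in names(est)) cat(sprintf("    %-10s %.4g\n", p, est[[p]]))
  }
  invisible(x)
}

#' Coerce fit results back to parameter objects
#'
#' @param fit a `fit_result`
#' @param template parameter object supplying any values the fit fixed
#' @return A [pk_parameters()] or [pd_parameters()] with the fitted values.
#' @export
as_pk_parameters <- function(fit, template = pk_parameters()) {
  stopifnot(fit$stage == "pk")
  th <- fit$estimates
  om <- template$omega
  for (p in names(om)) {
    v <- th[[paste0("om_", p)]]
    if (!is.null(v)) om[[p]] <- v
  }
  pk_parameters(CLp = th$CLp %||% template$CLp, CLt = th$CLt %||% template$CLt,
                Vc = th$Vc %||% template$Vc, Vt = th$Vt %||% template$Vt,
                theta_wt = th$theta_wt %||% template$theta_wt,
                theta_sex = th$theta_sex %||% template$theta_sex,
                omega = om, sigma_prop = th$sigma_prop)
}

#' @rdname as_pk_parameters
#' @export
as_pd_parameters <- function(fit, template = pd_parameters()) {
  stopifnot(fit$stage == "pd")
  th <- fit$estimates
  om <- template$omega
  for (p in names(om)) {
    v <- th[[paste0("om_", p)]]
    if (!is.null(v)) om[[p]] <- v
  }
  pd_parameters(kdeg = th$kdeg, kd = th$kd, kout = th$kout, HBASE = th$HBASE,
                MA = th$MA, MW = th$MW, MTmax = th$MTmax, FE4h = th$FE4h,
                FE10h = th$FE10h, kFE = th$kFE, omega = om,
                sigma_add = th$sigma_add)
}
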