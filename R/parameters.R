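#' Population pharmacokinetic parameters
#'
#' Container for the fixed effects, between-subject variability (BSV) and
#' residual error of the two-compartment intravenous-infusion PK model
#' \deqn{V_c \, dC_p/dt = R_{in}(t) - CL_p C_p - CL_t (C_p - C_t), \qquad
#'       V_t \, dC_t/dt = CL_t (C_p - C_t),}
#' with covariates entering multiplicatively: body weight allometrically on
#' the central volume (\code{Vc * (WT/70)^theta_wt}) and sex on central
#' clearance (\code{CLp * theta_sex^sex}, \code{sex = 1} for males).
#'
#' Defaults are the published population estimates for intravenous
#' ilaprazole. BSV terms are log-normal, \code{P_i = P * exp(eta)} with
#' \code{eta ~ N(0, omega^2)}; \code{omega} holds the log-scale standard
#' deviations (the reference variances 0.23, 1.17, 0.062 and 0.29 are stored
#' as their square roots). Residual error on concentrations is proportional,
#' \code{y = Cp * (1 + eps)}, \code{eps ~ N(0, sigma_prop^2)}.
#'
#' @param CLp central clearance (L/h)
#' @param CLt inter-compartmental clearance (L/h)
#' @param Vc central volume of distribution (L)
#' @param Vt peripheral volume of distribution (L)
#' @param theta_wt allometric exponent of body weight (referenced to 70 kg)
#'   on `Vc`
#' @param theta_sex multiplicative effect of male sex on `CLp`
#' @param omega named numeric vector of log-scale BSV standard deviations for
#'   `CLp`, `CLt`, `Vc`, `Vt` (zero switches a random effect off)
#' @param sigma_prop proportional residual error magnitude (SD scale)
#' @return An object of class `pk_parameters`.
#' @examples
#' pk <- pk_parameters()
#' pk$CLp
#' @export
pk_parameters <- function(CLp = 2.57, CLt = 4.59, Vc = 8.80, Vt = 3.65,
                          theta_wt = 1.35, theta_sex = 1.30,
                          omega = c(CLp = sqrt(0.23), CLt = sqrt(1.17),
                                    Vc = sqrt(0.062), Vt = sqrt(0.29)),
                          sigma_prop = 0.12) {
  omega <- .complete_named(omega, c("CLp", "CLt", "Vc", "Vt"))
  x <- list(CLp = CLp, CLt = CLt, Vc = Vc, Vt = Vt,
            theta_wt = theta_wt, theta_sex = theta_sex,
            omega = omega, sigma_prop = sigma_prop)
  validate_pk_parameters(x)
  structure(x, class = "pk_parameters")
}

validate_pk_parameters <- function(x) {
  pos <- c("CLp", "CLt", "Vc", "Vt", "theta_sex")
  for (p in pos) {
    if (!is.finite(x[[p]]) || x[[p]] <= 0)
      stop("pk_parameters: '", p, "' must be strictly positive", call. = FALSE)
  }
  if (!is.finite(x$theta_wt))
    stop("pk_parameters: 'theta_wt' must be finite", call. = FALSE)
  if (any(!is.finite(x$omega)) || any(x$omega < 0))
    stop("pk_parameters: 'omega' entries must be >= 0", call. = FALSE)
  if (!is.finite(x$sigma_prop) || x$sigma_prop < 0)
    stop("pk_parameters: 'sigma_prop' must be >= 0", call. = FALSE)
  invisible(x)
}

#' Gastric-acid pharmacodynamic parameters
#'
#' Container for the turnover/inhibition system describing intragastric
#' acidity under an irreversibly binding proton pump inhibitor:
#' \deqn{dE/dt = k_{deg}(1 - E) - k_d \, E \, C_p(t)}
#' \deqn{dH/dt = k_{out} H_{BASE} f_{circ}(t) E - k_{out} H}
#' where `E` is the relative pump (H+/K+-ATPase) activity (`E(0) = 1`), `H`
#' the latent intragastric H+ level in mM (`H(0) = HBASE`), and the synthesis
#' rate is tied to degradation by the drug-free steady state
#' (`ksyn = kdeg`). The circadian factor `f_circ` is a quartic bell of
#' amplitude `MA` and width `MW` centred at clock time `MTmax` (the nocturnal
#' acid surge); meals at 4 h and 10 h after the 08:00 dose dilute observed H+
#' (see [food_effect()]).
#'
#' Concentration units in the inhibition term: `kd` multiplies the plasma
#' concentration expressed in mg/L (equivalently micrograms/mL), the
#' customary modelling scale of the concentration variable; with the
#' reference value `kd = 18.24` per (mg/L) per h the pump collapses within
#' minutes at peak therapeutic exposure and recovers within a day, producing
#' the dose-graded, saturable acid suppression observed clinically.
#'
#' Defaults are the published population estimates for ilaprazole. BSV is
#' log-normal on `kdeg`, `kd`, `kout` (`omega` holds log-scale SDs; reference
#' variances 2.61, 1.38, 1.32 stored as square roots); the circadian and food
#' parameters are population-typical values without BSV. Residual error on
#' observed pH is additive with SD `sigma_add`.
#'
#' @param kdeg pump degradation rate constant (1/h)
#' @param kd irreversible inhibition efficacy (per (mg/L) per h)
#' @param kout H+ elimination rate constant (1/h)
#' @param HBASE baseline H+ level (mM); fixed, not estimated, in the
#'   reference analysis
#' @param MA amplitude of the nocturnal acid surge (dimensionless)
#' @param MW width of the nocturnal acid surge (h)
#' @param MTmax clock time of the surge peak (h)
#' @param FE4h,FE10h meal-dilution magnitudes for the 4-h and 10-h meals
#' @param kFE washout rate constant of the meal effect (1/h)
#' @param omega named numeric vector of log-scale BSV standard deviations for
#'   `kdeg`, `kd`, `kout`
#' @param sigma_add additive residual SD on observed pH (pH units)
#' @return An object of class `pd_parameters`.
#' @examples
#' pd <- pd_parameters()
#' pd$kd
#' @export
pd_parameters <- function(kdeg = 0.15, kd = 18.24, kout = 5.6, HBASE = 0.033,
                          MA = 28.48, MW = 0.99, MTmax = 22.38,
                          FE4h = 40.04, FE10h = 97.7, kFE = 0.64,
                          omega = c(kdeg = sqrt(2.61), kd = sqrt(1.38),
                                    kout = sqrt(1.32)),
                          sigma_add = 1.28) {
  omega <- .complete_named(omega, c("kdeg", "kd", "kout"))
  x <- list(kdeg = kdeg, kd = kd, kout = kout, HBASE = HBASE,
            MA = MA, MW = MW, MTmax = MTmax,
            FE4h = FE4h, FE10h = FE10h, kFE = kFE,
            omega = omega, sigma_add = sigma_add)
  validate_pd_parameters(x)
  structure(x, class = "pd_parameters")
}

validate_pd_parameters <- function(x) {
  pos <- c("kdeg", "kd", "kout", "HBASE", "MW", "kFE")
  for (p in pos) {
    if (!is.finite(x[[p]]) || x[[p]] <= 0)
      stop("pd_parameters: '", p, "' must be strictly positive", call. = FALSE)
  }
  for (p in c("MA", "FE4h", "FE10h")) {
    if (!is.finite(x[[p]]) || x[[p]] < 0)
      stop("pd_parameters: '", p, "' must be >= 0", call. = FALSE)
  }
  if (!is.finite(x$MTmax) || x$MTmax < 0 || x$MTmax >= 24)
    stop("pd_parameters: 'MTmax' must be a clock time in [0, 24)", call. = FALSE)
  if (any(!is.finite(x$omega)) || any(x$omega < 0))
    stop("pd_parameters: 'omega' entries must be >= 0", call. = FALSE)
  if (!is.finite(x$sigma_add) || x$sigma_add < 0)
    stop("pd_parameters: 'sigma_add' must be >= 0", call. = FALSE)
  invisible(x)
}

.complete_named <- function(x, nms) {
  if (is.null(names(x))) {
    if (length(x) != length(nms))
      stop("expected ", length(nms), " values or a named vector", call. = FALSE)
    names(x) <- nms
  }
  missing <- setdiff(nms, names(x))
  x <- c(x, setNames(rep(0, length(missing)), missing))
  x[nms]
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Population PK parameters (2-compartment IV infusion)\n")
  cat(sprintf("  CLp %.4g L/h  CLt %.4g L/h  Vc %.4g L  Vt %.4g L\n",
              x$CLp, x$CLt, x$Vc, x$Vt))
  cat(sprintf("  theta_wt %.4g (on Vc, ref 70 kg)  theta_sex %.4g (on CLp)\n",
              x$theta_wt, x$theta_sex))
  cat(sprintf("  BSV sd (log): %s\n",
              paste(sprintf("%s=%.3g", names(x$omega), x$omega), collapse = " ")))
  cat(sprintf("  proportional residual SD: %.3g\n", x$sigma_prop))
  invisible(x)
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat("Gastric-acid PD parameters (turnover + irreversible inhibition)\n")
  cat(sprintf("  kdeg %.4g /h  kd %.4g /(mg/L)/h  kout %.4g /h  HBASE %.4g mM\n",
              x$kdeg, x$kd, x$kout, x$HBASE))
  cat(sprintf("  surge: MA %.4g  MW %.4g h  MTmax %.4g h (clock)\n",
              x$MA, x$MW, x$MTmax))
  cat(sprintf("  meals: FE4h %.4g  FE10h %.4g  kFE %.4g /h\n",
              x$FE4h, x$FE10h, x$kFE))
  cat(sprintf("  BSV sd (log): %s\n",
              paste(sprintf("%s=%.3g", names(x$omega), x$omega), collapse = " ")))
  cat(sprintf("  additive pH residual SD: %.3g\n", x$sigma_add))
  invisible(x)
}
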