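#' Individual PK parameter values from covariates and random effects
#'
#' Applies the covariate and between-subject-variability model:
#' \deqn{CL_{p,i} = CL_p e^{\eta_1} \theta_{sex}^{sex}, \quad
#'       CL_{t,i} = CL_t e^{\eta_2}, \quad
#'       V_{c,i} = V_c e^{\eta_3} (WT/70)^{\theta_{wt}}, \quad
#'       V_{t,i} = V_t e^{\eta_4}.}
#'
#' @param pk a [pk_parameters()] object
#' @param weight body weight (kg)
#' @param sex 0 (female, reference) or 1 (male; carries the `theta_sex`
#'   multiplier on clearance)
#' @param eta numeric vector of length 4 of log-scale random effects, in the
#'   order (CLp, CLt, Vc, Vt)
#' @return Named numeric vector `c(CLp, CLt, Vc, Vt)` of individual values.
#' @examples
#' individual_parameters(pk_parameters(), weight = 70, sex = 0)
#' @export
individual_parameters <- function(pk, weight, sex, eta = numeric(4)) {
  stopifnot(inherits(pk, "pk_parameters"))
  if (!is.finite(weight) || weight <= 0)
    stop("weight must be strictly positive", call. = FALSE)
  if (!sex %in% c(0, 1)) stop("sex must be 0 or 1", call. = FALSE)
  if (length(eta) != 4L) stop("eta must have length 4", call. = FALSE)
  c(CLp = pk$CLp * exp(eta[1L]) * pk$theta_sex^sex,
    CLt = pk$CLt * exp(eta[2L]),
    Vc  = pk$Vc * exp(eta[3L]) * (weight / 70)^pk$theta_wt,
    Vt  = pk$Vt * exp(eta[4L]))
}

#' Closed-form plasma concentration for an infusion regimen
#'
#' Biexponential two-compartment solution with zero-order infusion input,
#' superposed over all dose events. For a single infusion of rate `R` mg/h
#' over `[0, T]` the central concentration is
#' \deqn{C_p(t) = R \sum_{i=1,2} \frac{c_i}{\lambda_i}
#'   \left(e^{-\lambda_i \max(0, t-T)} - e^{-\lambda_i t}\right), \quad t \ge 0,}
#' which covers both the on-infusion and washout phases. `Cp(t) = 0` before
#' each event starts, the response is linear in dose, and
#' `AUC(0, Inf) = Dose / CLp`.
#'
#' @param t times (h) at which to evaluate the concentration
#' @param doses data frame of dose events with columns `start_time`,
#'   `amount` (mg), `duration` (h) (see [dose_event()]), or a [regimen()]
#' @param pk_ind individual PK values: named vector with `CLp`, `CLt`, `Vc`,
#'   `Vt` (see [individual_parameters()])
#' @return Numeric vector of plasma concentrations (ng/mL).
#' @examples
#' pk_i <- individual_parameters(pk_parameters(), 70, 0)
#' pk_concentration(c(0.5, 2, 12), regimen(dose_event(0, 10)), pk_i)
#' @export
pk_concentration <- function(t, doses, pk_ind) {
  if (inherits(doses, "regimen")) doses <- doses$events
  stopifnot(all(c("start_time", "amount", "duration") %in% names(doses)))
  pk_conc2_cpp(t, doses$start_time, doses$amount, doses$duration,
               pk_ind[["CLp"]], pk_ind[["CLt"]], pk_ind[["Vc"]],
               pk_ind[["Vt"]])
}

#' Analytic area under the concentration-time curve
#'
#' `AUC(0, Inf) = total dose / CLp` for the linear two-compartment model.
#'
#' @inheritParams pk_concentration
#' @return AUC from 0 to infinity in ng*h/mL.
#' @export
pk_auc_inf <- function(doses, pk_ind) {
  if (inherits(doses, "regimen")) doses <- doses$events
  1000 * sum(doses$amount) / pk_ind[["CLp"]]
}
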