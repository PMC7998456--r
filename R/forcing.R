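#' Circadian gastric acid secretion factor
#'
#' Quartic-bell surge of nocturnal acid secretion,
#' \deqn{f(t) = 1 + \frac{MA}{((\Delta t / MW)^4 + 1)},}
#' where `dt` is the clock distance to the surge peak `MTmax`, wrapped onto
#' `[-12, 12]` h so the surge recurs every 24 h. The factor multiplies the
#' baseline H+ secretion rate: `f >= 1` everywhere, approaches 1 away from
#' the peak and attains `1 + MA` at `t = MTmax`.
#'
#' @param t clock time(s) in h (any real; interpreted modulo 24)
#' @param pd a [pd_parameters()] object (uses `MA`, `MW`, `MTmax`)
#' @return Dimensionless secretion factor, same length as `t`.
#' @examples
#' circadian_factor(22.38, pd_parameters())  # surge peak: 1 + MA
#' @export
circadian_factor <- function(t, pd) {
  .circadian(t, pd$MA, pd$MW, pd$MTmax)
}

.circadian <- function(clock, MA, MW, MTmax) {
  d <- ((clock - MTmax + 12) %% 24) - 12
  1 + MA / ((d / MW)^4 + 1)
}

#' Meal dilution factor for observed gastric acidity
#'
#' Meals taken 4 h and 10 h after the 08:00 dose (12:00 and 18:00 clock)
#' transiently dilute gastric H+. The factor is 1 while fasting and drops
#' discontinuously at each meal, recovering exponentially at rate `kFE`:
#' \deqn{F_e(t) = \cases{1 & t < 4 \cr
#'   (1 + FE_{4h} e^{-k_{FE}(t-4)})^{-1} & 4 \le t < 10 \cr
#'   (1 + FE_{4h} e^{-k_{FE}(t-4)} + FE_{10h} e^{-k_{FE}(t-10)})^{-1} & t \ge 10}}
#' On multi-day horizons `t` is reduced modulo 24 h so meals recur at the
#' same clock times each study day.
#'
#' @param t time(s) since the 08:00 dose (h, >= 0)
#' @param pd a [pd_parameters()] object (uses `FE4h`, `FE10h`, `kFE`)
#' @return Dilution factor in (0, 1], same length as `t`.
#' @examples
#' food_effect(c(2, 4, 10), pd_parameters())
#' @export
food_effect <- function(t, pd) {
  if (any(t < 0)) stop("food_effect is defined for t >= 0", call. = FALSE)
  .food_effect(t, pd$FE4h, pd$FE10h, pd$kFE)
}

.food_effect <- function(t, FE4h, FE10h, kFE) {
  td <- t %% 24
  lunch <- FE4h * exp(-kFE * (td - 4))
  dinner <- FE10h * exp(-kFE * (td - 10))
  ifelse(td < 4, 1,
         ifelse(td < 10, 1 / (1 + lunch), 1 / (1 + lunch + dinner)))
}

#' Observed gastric H+ after meal dilution
#'
#' The latent H+ level is multiplied by the meal dilution factor: meals lower
#' the observable H+ concentration (raise pH) without feeding back on the
#' acid-secretion dynamics.
#'
#' @param H latent H+ level (mM, > 0)
#' @param Fe dilution factor in (0, 1] (see [food_effect()])
#' @return Observed H+ level (mM).
#' @export
observed_h <- function(H, Fe) {
  if (any(H <= 0)) stop("H must be strictly positive", call. = FALSE)
  if (any(Fe <= 0 | Fe > 1)) stop("Fe must be in (0, 1]", call. = FALSE)
  H * Fe
}

#' Convert between H+ level (mM) and pH
#'
#' The model carries gastric H+ in mM and uses the convention
#' `pH = -log10(H in mM)`, chosen so that the fixed baseline `HBASE = 0.033`
#' mM maps to the physiological fasting minimum pH of about 1.48. The two
#' functions are strictly monotone inverses.
#'
#' @param H H+ level (mM, > 0)
#' @param pH pH value
#' @return `ph_from_h()` returns pH; `h_from_ph()` returns H+ in mM.
#' @examples
#' ph_from_h(0.033)
#' h_from_ph(ph_from_h(0.033))
#' @export
ph_from_h <- function(H) {
  if (any(!is.finite(H) | H <= 0))
    stop("H must be strictly positive and finite", call. = FALSE)
  -log10(H)
}

#' @rdname ph_from_h
#' @export
h_from_ph <- function(pH) {
  if (any(!is.finite(pH))) stop("pH must be finite", call. = FALSE)
  10^(-pH)
}
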