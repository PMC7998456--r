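#' Demographic configurations for virtual populations
#'
#' Body weight is drawn from a truncated normal distribution (inverse-CDF
#' sampling between the truncation quantiles), sex alternates male/female so
#' even sample sizes hit an exact 1:1 ratio. `demographics_internal()`
#' mirrors the internal clinical study population (mean 62.6 kg, SD 8.0,
#' range 52-79 kg); `demographics_simulation()` mirrors the virtual-trial
#' population (centre 70 kg, range 40-80 kg, median close to 70).
#'
#' @param center centre (untruncated mean) of the weight distribution (kg)
#' @param sd untruncated SD of the weight distribution (kg)
#' @param lower,upper truncation bounds (kg)
#' @return A `demographics` list.
#' @export
demographics <- function(center, sd, lower, upper) {
  if (!(lower < upper) || !(center > 0) || !(sd > 0))
    stop("inconsistent demographic bounds", call. = FALSE)
  structure(list(center = center, sd = sd, lower = lower, upper = upper),
            class = "demographics")
}

#' @rdname demographics
#' @export
demographics_internal <- function() demographics(62.6, 8.0, 52.0, 79.0)

#' @rdname demographics
#' @export
demographics_simulation <- function() demographics(70, 8, 40, 80)

#' Sample a virtual subject population
#'
#' @param n number of subjects (>= 1)
#' @param demo a [demographics()] configuration
#' @param seed optional integer seed; when given, sampling runs in an
#'   isolated RNG scope and is reproducible, otherwise the current RNG
#'   stream is used
#' @return Tibble with columns `ID`, `WT` (kg) and `SEX` (1 = male, 0 =
#'   female; odd IDs male so any even `n` is exactly 1:1).
#' @examples
#' sample_population(4, demographics_simulation(), seed = 1)
#' @export
sample_population <- function(n, demo = demographics_simulation(), seed = NULL) {
  stopifnot(n >= 1, inherits(demo, "demographics"))
  .with_seed(seed, {
    plo <- stats::pnorm(demo$lower, demo$center, demo$sd)
    phi <- stats::pnorm(demo$upper, demo$center, demo$sd)
    wt <- qnorm(plo + runif(n) * (phi - plo), demo$center, demo$sd)
    tibble::tibble(ID = seq_len(n), WT = wt,
                   SEX = as.integer(seq_len(n) %% 2L))
  })
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (requireNamespace("withr", quietly = TRUE)) {
    withr::with_seed(seed, expr)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
}

## Draw one subject's log-scale random effects for the named BSV terms.
.draw_eta <- function(omega) {
  rnorm(length(omega), 0, omega)
}
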