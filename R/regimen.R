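#' Intravenous infusion dose events and regimens
#'
#' A dose event is a constant-rate IV infusion of `amount` mg starting at
#' `start_time` h (simulation time; 0 is the 08:00 dose of day 1) lasting
#' `duration` h. A regimen is a labelled, time-sorted collection of dose
#' events with a simulation horizon. Overlapping infusions are allowed; the
#' linear PK superposes them.
#'
#' @param start_time infusion start (h, >= 0)
#' @param amount dose (mg, >= 0)
#' @param duration infusion duration (h, > 0); the default 0.5 h reflects
#'   typical short-infusion administration of IV proton pump inhibitors
#' @return `dose_event()` returns a one-row tibble; `regimen()` an object of
#'   class `regimen`.
#' @examples
#' regimen(dose_event(0, 20), label = "single 20 mg")
#' @export
dose_event <- function(start_time, amount, duration = 0.5) {
  stopifnot(is.numeric(start_time), is.numeric(amount), is.numeric(duration))
  if (any(amount < 0)) stop("dose amount must be >= 0", call. = FALSE)
  if (any(duration <= 0)) stop("infusion duration must be > 0", call. = FALSE)
  tibble::tibble(start_time = as.numeric(start_time),
                 amount = as.numeric(amount),
                 duration = as.numeric(duration),
                 route = "iv_infusion")
}

#' @rdname dose_event
#' @param ... dose events (tibbles from [dose_event()]) or a single data
#'   frame of events
#' @param label regimen label
#' @param horizon simulation horizon (h); defaults to the end of the last
#'   infusion rounded up to a whole day
#' @export
regimen <- function(..., label = "regimen", horizon = NULL) {
  ev <- list(...)
  events <- if (length(ev) == 1L && is.data.frame(ev[[1L]])) {
    tibble::as_tibble(ev[[1L]])
  } else {
    do.call(rbind, ev)
  }
  if (is.null(events) || nrow(events) == 0L)
    stop("a regimen needs at least one dose event", call. = FALSE)
  events <- events[order(events$start_time), , drop = FALSE]
  last_end <- max(events$start_time + events$duration)
  if (is.null(horizon)) horizon <- 24 * ceiling(last_end / 24)
  if (horizon < last_end)
    stop("regimen horizon ends before the last infusion", call. = FALSE)
  structure(list(label = label, events = events, horizon = horizon),
            class = "regimen")
}

#' Once-daily regimen constructor
#'
#' @param amounts dose amounts (mg), one per day, dosed at 24-h intervals
#'   starting at time 0 (08:00)
#' @param duration infusion duration (h)
#' @param label regimen label
#' @return A `regimen`.
#' @examples
#' daily_regimen(c(20, 10, 10), label = "loading dose")
#' @export
daily_regimen <- function(amounts, duration = 0.5, label = NULL) {
  if (is.null(label)) label <- paste(amounts, collapse = "/")
  regimen(dose_event(24 * (seq_along(amounts) - 1), amounts, duration),
          label = label, horizon = 24 * length(amounts))
}

#' The four reference three-day regimens
#'
#' The comparison set for regimen optimization: (1) 10 mg once daily for 3
#' days; (2) 20 mg then 5 mg once daily for 2 days; (3) 20 mg then 10 mg once
#' daily for 2 days (the recommended loading-dose regimen); (4) 20 mg once
#' daily for 3 days.
#'
#' @param duration infusion duration (h)
#' @return Named list of four `regimen` objects.
#' @export
reference_regimens <- function(duration = 0.5) {
  list(regimen1 = daily_regimen(c(10, 10, 10), duration, "10 mg qd x3"),
       regimen2 = daily_regimen(c(20, 5, 5), duration, "20 mg then 5 mg qd"),
       regimen3 = daily_regimen(c(20, 10, 10), duration, "20 mg then 10 mg qd"),
       regimen4 = daily_regimen(c(20, 20, 20), duration, "20 mg qd x3"))
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen '%s' (horizon %g h)\n", x$label, x$horizon))
  print(x$events)
  invisible(x)
}
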