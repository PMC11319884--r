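# INR monitoring-interval ladder: testing starts weekly; two consecutive
# in-range results at the current interval extend it by one week, up to a
# four-week (one month) cap; any dose change returns the patient to weekly
# checks until the dose stabilises again.

#' Construct a monitoring state
#'
#' @param interval_weeks Current testing interval, whole weeks in 1..4.
#' @param streak Number of consecutive in-range results accumulated at the
#'   current interval (0 or 1; the second consecutive result triggers the
#'   extension and resets the streak).
#' @return Object of class `"monitoring_state"`.
#' @export
monitoring_state <- function(interval_weeks = 1L, streak = 0L) {
  interval_weeks <- as.integer(interval_weeks)
  streak <- as.integer(streak)
  if (is.na(interval_weeks) || interval_weeks < 1L || interval_weeks > 4L) {
    stop("`interval_weeks` must be in 1..4", call. = FALSE)
  }
  if (is.na(streak) || !streak %in% c(0L, 1L)) {
    stop("`streak` must be 0 or 1", call. = FALSE)
  }
  structure(list(interval_weeks = interval_weeks, streak = streak),
            class = "monitoring_state")
}

#' Advance the monitoring interval after one INR result
#'
#' @param state A [monitoring_state()].
#' @param in_range Logical: was this INR within the patient's target range
#'   (therapeutic class, inclusive limits)?
#' @param dose_changed Logical: did this result trigger any dose
#'   adjustment (including holds)?
#' @param max_interval_weeks Cap on the interval (default 4 weeks, i.e.
#'   one month).
#' @return The updated [monitoring_state()]. A dose change resets to
#'   weekly testing; an out-of-range result resets the streak but keeps
#'   the interval; the second consecutive in-range result extends the
#'   interval by one week up to the cap.
#' @export
#' @examples
#' next_interval(monitoring_state(1, 1), in_range = TRUE, dose_changed = FALSE)
next_interval <- function(state, in_range, dose_changed,
                          max_interval_weeks = 4L) {
  stopifnot(inherits(state, "monitoring_state"))
  if (isTRUE(dose_changed)) {
    return(monitoring_state(1L, 0L))
  }
  if (!isTRUE(in_range)) {
    return(monitoring_state(state$interval_weeks, 0L))
  }
  if (state$streak == 0L) {
    return(monitoring_state(state$interval_weeks, 1L))
  }
  monitoring_state(min(state$interval_weeks + 1L, as.integer(max_interval_weeks)), 0L)
}

#' Trace the monitoring interval over a result sequence
#'
#' Folds [next_interval()] over a sequence of (in-range, dose-changed)
#' observations starting from weekly testing, and reports for each
#' observation the interval (weeks) that was in effect when it was taken.
#'
#' @param in_range Logical vector.
#' @param dose_changed Logical vector, same length.
#' @param ... Passed to [next_interval()].
#' @return Integer vector of interval weeks, one per observation (empty
#'   input gives an empty trace).
#' @export
#' @examples
#' schedule_trace(rep(TRUE, 4), rep(FALSE, 4))  # 1 1 2 2
schedule_trace <- function(in_range, dose_changed, ...) {
  if (length(in_range) != length(dose_changed)) {
    stop("`in_range` and `dose_changed` must have the same length",
         call. = FALSE)
  }
  state <- monitoring_state()
  out <- integer(length(in_range))
  for (k in seq_along(in_range)) {
    out[k] <- state$interval_weeks
    state <- next_interval(state, in_range[k], dose_changed[k], ...)
  }
  out
}
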