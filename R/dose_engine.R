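# Rule-based warfarin dose titration.
#
# Six general principles, applied in priority order against the patient's
# target range (lower, upper) with a 0.2 INR no-change margin:
#   1. INR within [lower - 0.2, upper + 0.2] -> dose unchanged
#   2. INR < lower - 0.2                     -> increase by 0.25 tablets
#   3. upper + 0.2 < INR <= 3                -> decrease by 0.25 tablets
#   4. INR > 3                               -> stop drug 1 day, recheck next day
#   5. holding and INR <= 3                  -> resume at pre-hold dose - 0.25
#   6. holding and INR > 3                   -> continue to hold, recheck next day
# Rule 4 takes precedence over rule 1's margin zone (for a range with
# upper = 3 the zone (3, 3.2] is still a hold); rule 3's window is then
# empty for ranges with upper >= 2.8, matching the printed inequality.

dose_actions <- c("NO_CHANGE", "INCREASE_QUARTER", "DECREASE_QUARTER",
                  "HOLD_ONE_DAY", "CONTINUE_HOLD", "RESUME_MINUS_QUARTER")

#' Construct a dose state
#'
#' @param dose Current warfarin dose in tablets/day; nonnegative multiple
#'   of 0.25. While holding, `dose` records the pre-hold dose.
#' @param holding Logical: is the drug currently stopped?
#' @param hold_start Date (or day number) the hold began; required when
#'   `holding` is `TRUE`.
#' @return Object of class `"dose_state"`.
#' @export
#' @examples
#' dose_state(1.25)
dose_state <- function(dose, holding = FALSE, hold_start = NULL) {
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("`dose` must be a nonnegative numeric scalar", call. = FALSE)
  }
  if (abs(dose / 0.25 - round(dose / 0.25)) > 1e-9) {
    stop("`dose` must be a multiple of 0.25 tablets (got ", dose, ")",
         call. = FALSE)
  }
  if (isTRUE(holding) && is.null(hold_start)) {
    stop("a holding state requires `hold_start`", call. = FALSE)
  }
  structure(list(dose = dose, holding = isTRUE(holding),
                 hold_start = hold_start),
            class = "dose_state")
}

#' Recommend the next warfarin dose from a single INR result
#'
#' Applies the six titration rules (see the package overview) to one INR
#' measurement given the patient's target range and current dose state.
#'
#' @param inr Positive INR value.
#' @param range A [target_range()] or `c(lower, upper)`.
#' @param state A [dose_state()].
#' @param margin No-change margin around the range limits (INR units,
#'   default 0.2).
#' @param hold_threshold INR above which the drug is stopped (default 3).
#' @return Object of class `"dose_recommendation"`: list with `action`
#'   (one of `NO_CHANGE`, `INCREASE_QUARTER`, `DECREASE_QUARTER`,
#'   `HOLD_ONE_DAY`, `CONTINUE_HOLD`, `RESUME_MINUS_QUARTER`), `new_dose`
#'   (tablets/day actually to be taken; 0 while holding), and
#'   `recheck_in_days` (1 for hold actions, `NA` otherwise -- routine
#'   recheck timing belongs to the monitoring schedule, see
#'   [next_interval()]).
#' @export
#' @examples
#' recommend_dose(1.4, target_range(1.7, 2.5), dose_state(1.0))
recommend_dose <- function(inr, range, state, margin = 0.2,
                           hold_threshold = 3) {
  range <- as_target_range(range)
  if (!is.numeric(inr) || length(inr) != 1L || is.na(inr) || inr <= 0) {
    stop("`inr` must be a positive scalar", call. = FALSE)
  }
  if (!inherits(state, "dose_state")) {
    stop("`state` must be a dose_state()", call. = FALSE)
  }
  if (state$holding && is.null(state$hold_start)) {
    stop("inconsistent state: holding without hold_start", call. = FALSE)
  }
  lo <- range[["lower"]]; hi <- range[["upper"]]
  quarter <- 0.25

  rec <- function(action, new_dose, recheck) {
    structure(list(action = action,
                   new_dose = max(0, new_dose),
                   recheck_in_days = recheck),
              class = "dose_recommendation")
  }

  if (state$holding) {
    if (inr <= hold_threshold) {
      return(rec("RESUME_MINUS_QUARTER", state$dose - quarter, NA_real_))
    }
    return(rec("CONTINUE_HOLD", 0, 1))
  }
  if (inr > hold_threshold) {
    return(rec("HOLD_ONE_DAY", 0, 1))
  }
  if (inr < lo - margin) {
    return(rec("INCREASE_QUARTER", state$dose + quarter, NA_real_))
  }
  if (inr > hi + margin) {
    return(rec("DECREASE_QUARTER", state$dose - quarter, NA_real_))
  }
  rec("NO_CHANGE", state$dose, NA_real_)
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf("%s -> %.2f tablets/day%s\n", x$action, x$new_dose,
              if (!is.na(x$recheck_in_days))
                sprintf(" (recheck in %d day)", as.integer(x$recheck_in_days))
              else ""))
  invisible(x)
}

# advance a dose_state by one recommendation; `date` marks a new hold start
apply_recommendation <- function(state, rec, date = NA) {
  switch(rec$action,
    NO_CHANGE = state,
    INCREASE_QUARTER = dose_state(rec$new_dose),
    DECREASE_QUARTER = dose_state(rec$new_dose),
    RESUME_MINUS_QUARTER = dose_state(rec$new_dose),
    HOLD_ONE_DAY = dose_state(state$dose, holding = TRUE, hold_start = date),
    CONTINUE_HOLD = state,
    stop("unknown action ", rec$action)
  )
}

#' Replay the titration rules over an INR measurement sequence
#'
#' Threads the hold state through consecutive measurements, producing one
#' recommendation per measurement. A multi-day hold resumes at the
#' pre-hold dose minus 0.25 tablets regardless of its length (the
#' reduction rule is applied once).
#'
#' @param dates Dates (or day numbers) of the measurements, sorted.
#' @param inr Positive INR values, same length as `dates`.
#' @param range A [target_range()] or `c(lower, upper)`.
#' @param initial Initial [dose_state()].
#' @param ... Passed to [recommend_dose()].
#' @return Data frame with one row per measurement: `date`, `inr`,
#'   `action`, `new_dose`, `holding` (state after the recommendation).
#'   The final [dose_state()] is attached as attribute `"final_state"`.
#' @export
#' @examples
#' run_titration(1:3, c(3.5, 3.2, 2.6), target_range(2, 3), dose_state(2))
run_titration <- function(dates, inr, range, initial, ...) {
  t <- as.numeric(dates)
  if (length(t) != length(inr)) {
    stop("`dates` and `inr` must have the same length", call. = FALSE)
  }
  if (is.unsorted(t)) stop("measurements must be sorted by date", call. = FALSE)
  state <- initial
  n <- length(t)
  action <- character(n); new_dose <- numeric(n); holding <- logical(n)
  for (k in seq_len(n)) {
    r <- recommend_dose(inr[k], range, state, ...)
    state <- apply_recommendation(state, r, date = dates[k])
    action[k] <- r$action
    new_dose[k] <- r$new_dose
    holding[k] <- state$holding
  }
  out <- data.frame(date = dates, inr = inr, action = action,
                    new_dose = new_dose, holding = holding,
                    stringsAsFactors = FALSE)
  attr(out, "final_state") <- state
  out
}
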