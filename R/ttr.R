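# Rosendaal linear-interpolation person-time arithmetic.
#
# For a segment between consecutive measurements (t1, i1) -> (t2, i2) the
# INR is modelled as linear in time; the segment's duration is split
# analytically at the crossing times of the range limits. Each segment
# contributes the half-open interval [t1, t2), so consecutive segments
# never double-count time.

# fraction of a linear segment a -> b spent strictly below c
.frac_below <- function(c, a, b) {
  out <- numeric(length(a))
  flat <- a == b
  out[flat] <- as.numeric(a[flat] < c)
  up <- !flat & b > a
  out[up] <- pmin(1, pmax(0, (c - a[up]) / (b[up] - a[up])))
  dn <- !flat & b < a
  out[dn] <- 1 - pmin(1, pmax(0, (c - a[dn]) / (b[dn] - a[dn])))
  out
}

#' Time in therapeutic range by Rosendaal linear interpolation
#'
#' Between each pair of consecutive INR measurements the INR is assumed to
#' change linearly with time; each day of the interval is attributed to
#' below-range, in-range (inclusive limits) or above-range according to the
#' interpolated value. Crossing times are computed in continuous days --
#' no rounding to whole days. TTR is the in-range fraction of all
#' interpolated person-time.
#'
#' Pairs separated by more than `max_gap_days` are excluded from the
#' person-time denominator (the classical formulation interpolates across
#' any gap, hence the unlimited default; a cap such as 56 days is common
#' in some registries). Duplicate same-day measurements are collapsed to
#' the last value of the day, with a message.
#'
#' @param dates Measurement dates: `Date` vector or numeric days. Must be
#'   non-decreasing.
#' @param inr Positive numeric vector of INR values, same length.
#' @param range A [target_range()] or `c(lower, upper)`.
#' @param max_gap_days Maximum inter-measurement gap interpolated across
#'   (days); `Inf` (default) disables the cap.
#' @return An object of class `"ttr_result"`: list with `days_below`,
#'   `days_in`, `days_above`, `ttr` (fraction in `[0, 1]`, `NA` when
#'   undefined), `n_pairs_used`, `n_pairs_excluded`, and `undefined`
#'   (logical; `TRUE` when fewer than 2 usable measurements leave a zero
#'   denominator).
#' @seealso [is_effective()], [ttr_by_patient()]
#' @export
#' @examples
#' rosendaal_ttr(c(0, 10), c(1.0, 3.0), target_range(2, 3))  # ttr = 0.5
rosendaal_ttr <- function(dates, inr, range, max_gap_days = Inf) {
  range <- as_target_range(range)
  t <- as.numeric(dates)
  if (length(t) != length(inr)) {
    stop("`dates` and `inr` must have the same length", call. = FALSE)
  }
  if (any(is.na(t)) || any(is.na(inr)) || any(inr <= 0)) {
    stop("INR values must be positive and dates non-missing", call. = FALSE)
  }
  if (is.unsorted(t)) {
    stop("measurements must be sorted by date", call. = FALSE)
  }
  # same-day duplicates: keep the last value of the day
  if (anyDuplicated(t)) {
    keep <- !duplicated(t, fromLast = TRUE)
    message(sum(!keep), " duplicate same-day measurement(s) dropped (kept last of day)")
    t <- t[keep]
    inr <- inr[keep]
  }

  empty <- function(n_excl) {
    structure(list(days_below = 0, days_in = 0, days_above = 0,
                   ttr = NA_real_, n_pairs_used = 0L,
                   n_pairs_excluded = as.integer(n_excl),
                   undefined = TRUE),
              class = "ttr_result")
  }
  n <- length(t)
  if (n < 2L) return(empty(0L))

  d <- diff(t)
  i1 <- inr[-n]
  i2 <- inr[-1L]
  use <- d <= max_gap_days & d > 0
  if (!any(use)) return(empty(sum(!use)))

  d <- d[use]; i1 <- i1[use]; i2 <- i2[use]
  lo <- range[["lower"]]; hi <- range[["upper"]]
  below <- d * .frac_below(lo, i1, i2)
  above <- d * .frac_below(-hi, -i1, -i2)  # x > hi  <=>  -x < -hi
  inr_in <- d - below - above
  total <- sum(d)
  structure(list(
    days_below = sum(below),
    days_in = sum(inr_in),
    days_above = sum(above),
    ttr = sum(inr_in) / total,
    n_pairs_used = sum(use),
    n_pairs_excluded = sum(!use) + 0L,
    undefined = FALSE
  ), class = "ttr_result")
}

#' @export
print.ttr_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("TTR undefined (fewer than 2 usable measurements)\n")
  } else {
    cat(sprintf(
      "Rosendaal TTR: %.1f%%  (below %.1f d, in %.1f d, above %.1f d over %d pairs)\n",
      100 * x$ttr, x$days_below, x$days_in, x$days_above, x$n_pairs_used))
  }
  invisible(x)
}

#' Effective-anticoagulation flag
#'
#' Conventionally, anticoagulation management is deemed effective when the
#' patient's TTR strictly exceeds 65%.
#'
#' @param ttr A `"ttr_result"` or a numeric TTR fraction (possibly `NA`).
#' @param threshold TTR fraction that must be strictly exceeded
#'   (default 0.65).
#' @return List with `effective` (logical, `NA` when TTR is undefined) and
#'   `threshold`.
#' @export
#' @examples
#' is_effective(0.716)
is_effective <- function(ttr, threshold = 0.65) {
  val <- if (inherits(ttr, "ttr_result")) ttr$ttr else as.numeric(ttr)
  eff <- ifelse(is.na(val), NA, val > threshold)
  list(effective = eff, threshold = threshold)
}

#' Per-patient TTR over an INR log
#'
#' Applies [rosendaal_ttr()] patient by patient, resolving each patient's
#' target range from the registry's indication column.
#'
#' @param inr_log Data frame with columns `patient_id`, `date`, `inr`
#'   (as produced by [read_inr_log()] or [simulate_cohort()]).
#' @param registry Data frame with columns `patient_id`, `indications`
#'   (semicolon-separated codes) and optionally `arm`.
#' @param ranges Named list of target ranges (default
#'   [default_target_ranges()]).
#' @param max_gap_days Passed to [rosendaal_ttr()].
#' @param threshold Effectiveness threshold passed to [is_effective()].
#' @return Data frame, one row per registry patient: `patient_id`, `arm`
#'   (if present), `days_below`, `days_in`, `days_above`, `ttr`,
#'   `effective`.
#' @export
ttr_by_patient <- function(inr_log, registry, ranges = default_target_ranges(),
                           max_gap_days = Inf, threshold = 0.65) {
  stopifnot(all(c("patient_id", "date", "inr") %in% names(inr_log)),
            all(c("patient_id", "indications") %in% names(registry)))
  idx <- split(seq_len(nrow(inr_log)), inr_log$patient_id)
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    pid <- registry$patient_id[i]
    ind <- strsplit(as.character(registry$indications[i]), ";", fixed = TRUE)[[1L]]
    rng <- resolve_target_range(ind, ranges)
    sub <- inr_log[idx[[pid]], , drop = FALSE]
    sub <- sub[order(as.numeric(sub$date)), , drop = FALSE]
    res <- rosendaal_ttr(sub$date, sub$inr, rng, max_gap_days = max_gap_days)
    data.frame(patient_id = pid,
               arm = if ("arm" %in% names(registry)) registry$arm[i] else NA_character_,
               days_below = res$days_below, days_in = res$days_in,
               days_above = res$days_above, ttr = res$ttr,
               effective = is_effective(res, threshold)$effective,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
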