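#' Anticoagulation indication codes
#'
#' The five anticoagulation indications the management engines recognise.
#'
#' @return Character vector of valid indication codes.
#' @export
#' @examples
#' indication_codes()
indication_codes <- function() {
  c("AORTIC_VALVE", "MITRAL_VALVE", "TRICUSPID_VALVE",
    "ATRIAL_FIBRILLATION", "VTE")
}

#' Ordered INR classification levels
#'
#' Five levels partitioning the positive INR axis, from extreme
#' subtherapeutic to extreme supratherapeutic.
#'
#' @return Character vector of the five class labels, in increasing order
#'   of anticoagulation intensity.
#' @export
inr_class_levels <- function() {
  c("EXTREME_SUB", "SUB", "THERAPEUTIC", "SUPRA", "EXTREME_SUPRA")
}

#' Construct an INR target range
#'
#' @param lower,upper Numeric scalars, the therapeutic interval limits in
#'   INR units; `0 < lower < upper` is required.
#' @return An object of class `"target_range"`: a named numeric vector with
#'   elements `lower` and `upper`.
#' @export
#' @examples
#' target_range(2, 3)
target_range <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      length(lower) != 1L || length(upper) != 1L ||
      is.na(lower) || is.na(upper)) {
    stop("`lower` and `upper` must be non-missing numeric scalars",
         call. = FALSE)
  }
  if (!(lower > 0 && lower < upper)) {
    stop("target range requires 0 < lower < upper (got ",
         lower, ", ", upper, ")", call. = FALSE)
  }
  structure(c(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "target_range")
}

#' @export
print.target_range <- function(x, ...) {
  cat(sprintf("INR target range: %.2f-%.2f\n", x[["lower"]], x[["upper"]]))
  invisible(x)
}

as_target_range <- function(x) {
  if (inherits(x, "target_range")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(target_range(x[[1L]], x[[2L]]))
  stop("cannot interpret `range`; supply target_range() or c(lower, upper)",
       call. = FALSE)
}

#' Built-in indication-to-target-range table
#'
#' Default therapeutic INR intervals per indication. The valve ranges
#' follow the originating centre's clinical practice (deliberately narrower
#' than some guideline ranges for mechanical valves); deployments may
#' override them via a JSON configuration, see [read_ranges_config()].
#'
#' @return Named list mapping each indication code to a
#'   [target_range()] object.
#' @export
#' @examples
#' default_target_ranges()[["ATRIAL_FIBRILLATION"]]
default_target_ranges <- function() {
  list(
    AORTIC_VALVE        = target_range(1.5, 2.0),
    MITRAL_VALVE        = target_range(1.7, 2.5),
    TRICUSPID_VALVE     = target_range(2.0, 2.5),
    ATRIAL_FIBRILLATION = target_range(2.0, 3.0),
    VTE                 = target_range(2.0, 3.0)
  )
}

#' Resolve the target range for a patient with one or more indications
#'
#' When a patient carries several anticoagulation indications, the most
#' intense (highest) target range governs management: the range with the
#' maximal upper limit is chosen, ties broken by the maximal lower limit.
#'
#' @param indications Character vector of indication codes
#'   (see [indication_codes()]); must be nonempty.
#' @param ranges Named list of [target_range()] objects keyed by indication
#'   code; defaults to [default_target_ranges()].
#' @return A [target_range()].
#' @export
#' @examples
#' resolve_target_range("AORTIC_VALVE")
#' resolve_target_range(c("MITRAL_VALVE", "ATRIAL_FIBRILLATION"))
resolve_target_range <- function(indications, ranges = default_target_ranges()) {
  if (length(indications) == 0L || all(is.na(indications))) {
    stop("cannot resolve a target range: empty indication list", call. = FALSE)
  }
  indications <- unique(as.character(indications))
  unknown <- setdiff(indications, names(ranges))
  if (length(unknown) > 0L) {
    stop("unknown indication code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cand <- ranges[indications]
  uppers <- vapply(cand, function(r) r[["upper"]], numeric(1))
  lowers <- vapply(cand, function(r) r[["lower"]], numeric(1))
  top <- which(uppers == max(uppers))
  pick <- top[which.max(lowers[top])]
  as_target_range(cand[[pick]])
}

#' Classify INR values into the five-level scheme
#'
#' Partitions the positive INR axis relative to a target range
#' `(lower, upper)` with a fixed margin (default 0.2 INR units):
#'
#' * `EXTREME_SUB`:  INR < lower - margin
#' * `SUB`:          lower - margin <= INR < lower
#' * `THERAPEUTIC`:  lower <= INR <= upper (both limits inclusive)
#' * `SUPRA`:        upper < INR <= 4.5
#' * `EXTREME_SUPRA`: INR > 4.5
#'
#' With `upper_margin_therapeutic = TRUE` the band `(upper, upper + margin]`
#' is counted as `THERAPEUTIC` instead of `SUPRA`, mirroring the dose
#' engine's no-change zone; the default keeps the five classes a strict
#' partition anchored at the printed range limits.
#'
#' @param inr Numeric vector of INR values; all must be positive.
#' @param range A [target_range()] or `c(lower, upper)`.
#' @param margin Width of the sub-band below the lower limit (INR units).
#' @param extreme_supra_threshold INR above which values are classed
#'   `EXTREME_SUPRA` (default 4.5).
#' @param upper_margin_therapeutic Logical policy switch, see Details.
#' @return Factor with levels [inr_class_levels()], same length as `inr`.
#' @export
#' @examples
#' classify_inr(c(1.79, 2.0, 3.4, 4.6), target_range(2, 3))
classify_inr <- function(inr, range, margin = 0.2,
                         extreme_supra_threshold = 4.5,
                         upper_margin_therapeutic = FALSE) {
  range <- as_target_range(range)
  if (!is.numeric(inr) || any(is.na(inr)) || any(inr <= 0)) {
    stop("`inr` must be positive and non-missing", call. = FALSE)
  }
  lo <- range[["lower"]]
  hi <- range[["upper"]]
  hi_eff <- if (upper_margin_therapeutic) hi + margin else hi
  lv <- inr_class_levels()
  out <- character(length(inr))
  out[inr < lo - margin] <- "EXTREME_SUB"
  out[inr >= lo - margin & inr < lo] <- "SUB"
  out[inr >= lo & inr <= hi_eff] <- "THERAPEUTIC"
  out[inr > hi_eff & inr <= extreme_supra_threshold] <- "SUPRA"
  out[inr > extreme_supra_threshold] <- "EXTREME_SUPRA"
  factor(out, levels = lv, ordered = TRUE)
}
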