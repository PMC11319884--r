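# File interchange: CSV readers with row-level validation, the versioned
# JSON target-range configuration, cohort writers and the deterministic
# report writer with a sha256 manifest. Dates are ISO-8601 calendar dates;
# all durations are whole days.

parse_iso_date <- function(x) as.Date(x, format = "%Y-%m-%d")

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a per-patient INR log
#'
#' Reads a CSV with columns `patient_id`, `date` (ISO-8601), `inr` and
#' optionally `dose_tablets`. Rows are validated individually -- an
#' unparseable date or a non-positive INR is an error naming the
#' offending line. Records are sorted by date within patient; duplicate
#' same-day values are collapsed to the last one of the day, with a
#' message giving the count.
#'
#' @param path Path to the CSV file.
#' @return Data frame `patient_id`, `date` (`Date`), `inr`,
#'   `dose_tablets` (`NA` when absent).
#' @export
read_inr_log <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "date", "inr"))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  date <- parse_iso_date(df$date)
  bad <- which(is.na(date))
  if (length(bad) > 0L) {
    stop(path, ": unparseable date on line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  inr <- suppressWarnings(as.numeric(df$inr))
  bad <- which(is.na(inr) | inr <= 0)
  if (length(bad) > 0L) {
    stop(path, ": invalid INR (must be a positive number) on line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  dose <- if ("dose_tablets" %in% names(df)) {
    suppressWarnings(as.numeric(df$dose_tablets))
  } else {
    rep(NA_real_, nrow(df))
  }
  out <- data.frame(patient_id = df$patient_id, date = date, inr = inr,
                    dose_tablets = dose, stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$date), , drop = FALSE]
  dup <- duplicated(out[, c("patient_id", "date")], fromLast = TRUE)
  if (any(dup)) {
    message(sum(dup), " duplicate same-day measurement(s) dropped (kept last of day)")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a patient registry
#'
#' CSV with columns `patient_id`, `arm`, `indications` (semicolon-joined
#' codes), `enroll_date`, `exit_date`, and optionally `died`.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame with parsed dates.
#' @export
read_registry <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "arm", "indications",
                                  "enroll_date", "exit_date"))
  line <- seq_len(nrow(df)) + 1L
  for (col in c("enroll_date", "exit_date")) {
    d <- parse_iso_date(df[[col]])
    bad <- which(is.na(d))
    if (length(bad) > 0L) {
      stop(path, ": unparseable ", col, " on line(s) ",
           paste(line[bad], collapse = ", "), call. = FALSE)
    }
    df[[col]] <- d
  }
  if (anyDuplicated(df$patient_id)) {
    stop(path, ": duplicated patient_id(s)", call. = FALSE)
  }
  df$died <- if ("died" %in% names(df)) as.logical(df$died) else FALSE
  df
}

#' Read a clinical event log
#'
#' CSV with columns `patient_id`, `type`, `subtype`, `date`.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame with parsed dates.
#' @export
read_events <- function(path) {
  df <- .read_csv_checked(path, c("patient_id", "type", "date"))
  line <- seq_len(nrow(df)) + 1L
  d <- parse_iso_date(df$date)
  bad <- which(is.na(d))
  if (length(bad) > 0L) {
    stop(path, ": unparseable date on line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  df$date <- d
  bad <- which(!df$type %in% event_types)
  if (length(bad) > 0L) {
    stop(path, ": unknown event type on line(s) ",
         paste(line[bad], collapse = ", "), call. = FALSE)
  }
  if (!"subtype" %in% names(df)) df$subtype <- NA_character_
  df
}

#' Read (or default) the target-range configuration
#'
#' The indication-to-range table ships as a versioned JSON file mapping
#' each indication code to `[lower, upper]`; deployments may override it.
#' Unknown indication keys are rejected.
#'
#' @param path Path to a JSON config; `NULL` loads the packaged default
#'   (which encodes [default_target_ranges()]).
#' @return Named list of [target_range()] objects; the config version is
#'   attached as attribute `"version"`.
#' @export
read_ranges_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "target_ranges.json", package = "anticoagr")
  }
  if (!file.exists(path)) stop("ranges config not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path)
  if (is.null(cfg$ranges)) stop(path, ": no `ranges` entry", call. = FALSE)
  unknown <- setdiff(names(cfg$ranges), indication_codes())
  if (length(unknown) > 0L) {
    stop(path, ": unknown indication key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- lapply(cfg$ranges, function(v) target_range(v[[1L]], v[[2L]]))
  attr(out, "version") <- cfg$version
  out
}

#' Write a simulated cohort to CSV
#'
#' Writes `registry.csv`, `inr_log.csv` and `events.csv` plus a
#' `provenance.json` embedding the full simulation configuration, so a
#' cohort is reproducible from its output directory alone.
#'
#' @param cohort A `"cohort"` from [simulate_cohort()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(registry = file.path(out_dir, "registry.csv"),
             inr_log = file.path(out_dir, "inr_log.csv"),
             events = file.path(out_dir, "events.csv"),
             provenance = file.path(out_dir, "provenance.json"))
  utils::write.csv(cohort$registry, paths[["registry"]], row.names = FALSE)
  utils::write.csv(cohort$inr_log, paths[["inr_log"]], row.names = FALSE)
  utils::write.csv(cohort$events, paths[["events"]], row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config), paths[["provenance"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write an analysis report with a deterministic manifest
#'
#' Writes each table (data frame) as CSV and each set of curve points as
#' CSV under `out_dir`, then a `manifest.csv` listing every file with its
#' sha256 digest. Rerunning on identical inputs yields an identical
#' manifest.
#'
#' @param tables Named list of data frames.
#' @param curves Named list of `"event_curves"` objects (or data frames
#'   of curve points); may be empty.
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame (`file`, `sha256`), invisibly also
#'   written to `manifest.csv`.
#' @export
write_report <- function(tables, curves = list(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir,
                                 call. = FALSE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), f, row.names = FALSE)
    files <- c(files, f)
  }
  for (nm in names(curves)) {
    obj <- curves[[nm]]
    pts <- if (inherits(obj, "event_curves")) {
      fit <- obj$fit
      strata <- if (is.null(fit$strata)) {
        stats::setNames(length(fit$time), "all")
      } else {
        fit$strata
      }
      data.frame(stratum = rep(names(strata), strata),
                 time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, survival = fit$surv)
    } else {
      as.data.frame(obj)
    }
    f <- file.path(out_dir, paste0(nm, "_curve.csv"))
    utils::write.csv(pts, f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- data.frame(
    file = basename(files),
    sha256 = vapply(files, function(f) {
      digest::digest(f, algo = "sha256", file = TRUE)
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
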