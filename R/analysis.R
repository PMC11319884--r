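# Cohort comparison layer: normality-gated two-group tests, 2x2
# contingency analysis with the conventional expected-count gate,
# INR-distribution and clinical-event tables, Kaplan-Meier curves with
# log-rank tests, and two-proportion sample size with attrition inflation.
#
# Percentages are always recomputed from counts (never stored), and group
# denominators are always taken from the data supplied at analysis time.

event_types <- c("MINOR_BLEED", "SEVERE_BLEED", "THROMBOEMBOLIC", "DEATH")

group_comparison <- function(metric, summaries, test, p_value,
                             statistic = NA_real_) {
  structure(list(metric = metric, summaries = summaries, test = test,
                 p_value = p_value, statistic = statistic),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s  [%s, p = %s]\n", x$metric,
              paste(names(x$summaries), x$summaries, sep = " ",
                    collapse = " vs "),
              x$test, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

ks_normal_p <- function(x) {
  if (length(x) < 3L || stats::sd(x) == 0) return(0)
  suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
}

#' Compare a continuous variable between two groups
#'
#' Gates the test choice on a Kolmogorov-Smirnov check of normality in
#' each group (against a normal with sample-estimated mean and SD): if
#' both groups pass, a pooled-variance Student t test is used and the
#' groups are summarised as mean (SD); otherwise a Mann-Whitney U test
#' with median (IQR) summaries.
#'
#' @param x,y Numeric samples for the two groups.
#' @param labels Character pair naming the groups.
#' @param metric Name of the variable being compared.
#' @param alpha_normality Significance level of the normality gate.
#' @return A `"group_comparison"`; `test` is `"T_TEST"`,
#'   `"MANN_WHITNEY"`, or `"INSUFFICIENT"` when either group has n < 3.
#' @export
#' @examples
#' compare_continuous(rnorm(50), rnorm(50, 0.5))
compare_continuous <- function(x, y, labels = c("group1", "group2"),
                               metric = "value", alpha_normality = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L) {
    return(group_comparison(metric, stats::setNames(c(NA, NA), labels),
                            "INSUFFICIENT", NA_real_))
  }
  normal <- ks_normal_p(x) > alpha_normality && ks_normal_p(y) > alpha_normality
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    summ <- sprintf("%.1f (%.1f)", c(mean(x), mean(y)),
                    c(stats::sd(x), stats::sd(y)))
    group_comparison(metric, stats::setNames(summ, labels), "T_TEST",
                     tt$p.value, unname(tt$statistic))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    iqr <- function(v) sprintf("%.1f (%.1f-%.1f)", stats::median(v),
                               stats::quantile(v, 0.25), stats::quantile(v, 0.75))
    group_comparison(metric, stats::setNames(c(iqr(x), iqr(y)), labels),
                     "MANN_WHITNEY", wt$p.value, unname(wt$statistic))
  }
}

#' Compare a 2x2 contingency table
#'
#' Uses the Fisher exact test when any expected or observed cell count is
#' below 5, otherwise a chi-square test (Yates continuity correction by
#' default, matching common statistical-software behaviour for 2x2
#' tables).
#'
#' @param tab 2x2 matrix of nonnegative integer counts (groups in
#'   columns).
#' @param correct Apply the continuity correction in the chi-square
#'   branch.
#' @param metric Name for the comparison.
#' @return A `"group_comparison"`; `test` is `"CHI_SQUARE"`,
#'   `"FISHER_EXACT"`, or `"DEGENERATE"` for a zero-margin table.
#' @export
#' @examples
#' compare_categorical(matrix(c(31, 226, 17, 242), 2))
compare_categorical <- function(tab, correct = TRUE, metric = "counts") {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) || any(tab != round(tab))) {
    stop("`tab` must be a 2x2 matrix of nonnegative integer counts",
         call. = FALSE)
  }
  labels <- colnames(tab)
  if (is.null(labels)) labels <- c("group1", "group2")
  summ <- stats::setNames(sprintf("%d/%d", tab[1, ], colSums(tab)), labels)
  if (any(colSums(tab) == 0) || sum(tab) == 0) {
    return(group_comparison(metric, summ, "DEGENERATE", NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5) || any(tab < 5)) {
    ft <- stats::fisher.test(tab)
    group_comparison(metric, summ, "FISHER_EXACT", ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    group_comparison(metric, summ, "CHI_SQUARE", ct$p.value,
                     unname(ct$statistic))
  }
}

#' INR distribution table from per-class counts
#'
#' Builds the five-level INR distribution table (counts, percentages
#' recomputed from counts at analysis time, and a per-row class-vs-rest
#' 2x2 test) from a 5 x 2 count matrix.
#'
#' @param counts 5 x 2 integer matrix; rows are [inr_class_levels()]
#'   (in order), columns the two arms.
#' @param correct Continuity correction for the chi-square branch.
#' @return Object of class `"inr_distribution"`: data frame with columns
#'   `class`, `n_<arm>`, `pct_<arm>` for each arm, `test`, `p_value`.
#'   Column totals are attached as attribute `"arm_totals"`.
#' @export
inr_table_from_counts <- function(counts, correct = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 5L || ncol(counts) != 2L) {
    stop("`counts` must be 5 x 2 (five INR classes, two arms)", call. = FALSE)
  }
  if (is.null(colnames(counts))) colnames(counts) <- c("group1", "group2")
  totals <- colSums(counts)
  pct <- sweep(counts, 2L, totals, function(n, tot) ifelse(tot > 0, 100 * n / tot, 0))
  tests <- lapply(seq_len(5L), function(r) {
    if (sum(counts) == 0) return(group_comparison("row", NULL, "DEGENERATE", NA_real_))
    tab <- rbind(counts[r, ], totals - counts[r, ])
    colnames(tab) <- colnames(counts)
    compare_categorical(tab, correct = correct, metric = inr_class_levels()[r])
  })
  out <- data.frame(class = inr_class_levels(), stringsAsFactors = FALSE)
  for (j in seq_len(2L)) {
    out[[paste0("n_", colnames(counts)[j])]] <- counts[, j]
    out[[paste0("pct_", colnames(counts)[j])]] <- round(pct[, j], 1)
  }
  out$test <- vapply(tests, function(g) g$test, character(1))
  out$p_value <- vapply(tests, function(g) g$p_value, numeric(1))
  structure(out, arm_totals = totals, class = c("inr_distribution", "data.frame"))
}

#' INR distribution by arm from an INR log
#'
#' Classifies every INR record with [classify_inr()] against the
#' patient's indication-resolved range and tabulates per-arm counts and
#' percentages with per-row tests. Patients in the log but absent from
#' the registry are excluded with a message.
#'
#' @param inr_log Data frame `patient_id`, `date`, `inr`.
#' @param registry Data frame `patient_id`, `arm`, `indications`.
#' @param ranges Indication-to-range table.
#' @param arms Character pair giving the column order of the table.
#' @param ... Passed to [classify_inr()].
#' @return An `"inr_distribution"`, see [inr_table_from_counts()].
#' @export
inr_distribution <- function(inr_log, registry,
                             ranges = default_target_ranges(),
                             arms = c("NON_WEB", "WEB"), ...) {
  known <- inr_log$patient_id %in% registry$patient_id
  if (any(!known)) {
    message(sum(!known), " INR record(s) with unregistered patient id excluded")
    inr_log <- inr_log[known, , drop = FALSE]
  }
  counts <- matrix(0L, 5L, 2L,
                   dimnames = list(inr_class_levels(), arms))
  idx <- split(seq_len(nrow(inr_log)), inr_log$patient_id)
  for (i in seq_len(nrow(registry))) {
    pid <- registry$patient_id[i]
    if (is.null(idx[[pid]])) next
    sub <- inr_log[idx[[pid]], , drop = FALSE]
    if (nrow(sub) == 0L) next
    ind <- strsplit(as.character(registry$indications[i]), ";", fixed = TRUE)[[1L]]
    rng <- resolve_target_range(ind, ranges)
    cl <- classify_inr(sub$inr, rng, ...)
    counts[, registry$arm[i]] <- counts[, registry$arm[i]] +
      as.integer(table(cl))
  }
  inr_table_from_counts(counts)
}

#' Clinical event summary table
#'
#' Per event type, counts the patients with at least one event (first
#' event per patient per type counts once), computes per-arm percentages
#' with denominators from the registry, and tests each type with
#' [compare_categorical()].
#'
#' @param events Data frame `patient_id`, `type`, `date`.
#' @param registry Data frame `patient_id`, `arm`.
#' @param arms Character pair giving the column order.
#' @param types Event types to tabulate.
#' @return Data frame `type`, `n_<arm>`, `pct_<arm>`, `test`, `p_value`.
#' @export
event_summary <- function(events, registry, arms = c("NON_WEB", "WEB"),
                          types = event_types) {
  unknown <- setdiff(unique(events$patient_id), registry$patient_id)
  if (length(unknown) > 0L) {
    stop("event(s) recorded for unknown patient id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  denom <- vapply(arms, function(a) sum(registry$arm == a), integer(1))
  rows <- lapply(types, function(ty) {
    pats <- unique(events$patient_id[events$type == ty])
    n <- vapply(arms, function(a) {
      sum(registry$arm[match(pats, registry$patient_id)] == a)
    }, integer(1))
    tab <- rbind(n, denom - n)
    colnames(tab) <- arms
    cmp <- compare_categorical(tab, metric = ty)
    out <- data.frame(type = ty, stringsAsFactors = FALSE)
    for (j in seq_along(arms)) {
      out[[paste0("n_", arms[j])]] <- n[j]
      out[[paste0("pct_", arms[j])]] <-
        round(ifelse(denom[j] > 0, 100 * n[j] / denom[j], 0), 1)
    }
    out$test <- cmp$test
    out$p_value <- cmp$p_value
    out
  })
  do.call(rbind, rows)
}

#' Cumulative event curves and log-rank comparison
#'
#' Kaplan-Meier estimate of time to first event of the given type per
#' arm, censoring at exit (or death from another cause), with a log-rank
#' test between arms.
#'
#' @param events Data frame `patient_id`, `type`, `date`.
#' @param registry Data frame `patient_id`, `arm`, `enroll_date`,
#'   `exit_date`.
#' @param type Event type to analyse.
#' @return Object of class `"event_curves"`: list with `fit`
#'   (a [survival::survfit] object), `p_value` (log-rank; `NA` when no
#'   events occurred in either arm), `n_events` and `data` (the
#'   per-patient time/status frame).
#' @export
cumulative_event_curves <- function(events, registry, type = "MINOR_BLEED") {
  unknown <- setdiff(unique(events$patient_id), registry$patient_id)
  if (length(unknown) > 0L) {
    stop("event(s) recorded for unknown patient id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ev <- events[events$type == type, , drop = FALSE]
  first <- tapply(as.numeric(ev$date), ev$patient_id, min)
  enroll <- as.numeric(registry$enroll_date)
  exit <- as.numeric(registry$exit_date)
  etime <- first[registry$patient_id]
  status <- as.integer(!is.na(etime))
  time <- ifelse(status == 1L, etime - enroll, exit - enroll)
  dat <- data.frame(patient_id = registry$patient_id, arm = registry$arm,
                    time = as.numeric(time), status = status,
                    stringsAsFactors = FALSE)
  fit <- survival::survfit(survival::Surv(time, status) ~ arm, data = dat)
  p <- NA_real_
  if (sum(status) > 0L && length(unique(dat$arm)) > 1L) {
    sd <- survival::survdiff(survival::Surv(time, status) ~ arm, data = dat)
    p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  }
  structure(list(fit = fit, p_value = p, n_events = sum(status), data = dat),
            class = "event_curves")
}

#' @export
print.event_curves <- function(x, ...) {
  cat(sprintf("Time-to-first-event curves: %d events; log-rank p = %s\n",
              x$n_events, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Enrollment target under expected attrition
#'
#' Inflates a required evaluable sample by the expected loss fraction:
#' `n_enrolled = ceiling(n_evaluable / (1 - attrition))` per group.
#'
#' @param n_evaluable Required evaluable patients per group.
#' @param attrition Expected loss-to-follow-up fraction in `[0, 1)`.
#' @return List with `n_enrolled_per_group` and `n_total` (both groups).
#' @export
#' @examples
#' enrollment_for_attrition(206, 0.20)  # 258 per group, 516 total
enrollment_for_attrition <- function(n_evaluable, attrition) {
  if (attrition < 0 || attrition >= 1) {
    stop("`attrition` must lie in [0, 1)", call. = FALSE)
  }
  n_enrolled <- ceiling(n_evaluable / (1 - attrition))
  list(n_enrolled_per_group = n_enrolled, n_total = 2L * n_enrolled)
}

#' Two-proportion sample size with attrition inflation
#'
#' Normal-approximation (pooled-variance) sample size for detecting a
#' difference between two proportions at two-sided level `alpha` with the
#' given power, inflated for expected attrition.
#'
#' @param p1,p2 Anticipated proportions, `0 < p2 < p1 < 1` (superiority
#'   framing).
#' @param alpha Two-sided significance level.
#' @param power Desired power (1 - beta).
#' @param attrition Expected loss fraction in `[0, 1)`.
#' @return Object of class `"sample_size_result"`: list with `alpha`,
#'   `power`, `p1`, `p2`, `n_evaluable_per_group`, `attrition`,
#'   `n_enrolled_per_group`, `n_total`.
#' @export
#' @examples
#' sample_size_two_proportions(0.731, 0.66, attrition = 0.20)
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80,
                                        attrition = 0) {
  if (!(p2 > 0 && p1 < 1 && p1 > p2)) {
    stop("superiority framing requires 0 < p2 < p1 < 1", call. = FALSE)
  }
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  pbar <- (p1 + p2) / 2
  num <- (za * sqrt(2 * pbar * (1 - pbar)) +
            zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2
  n_eval <- ceiling(num / (p1 - p2)^2)
  infl <- enrollment_for_attrition(n_eval, attrition)
  structure(list(alpha = alpha, power = power, p1 = p1, p2 = p2,
                 n_evaluable_per_group = n_eval, attrition = attrition,
                 n_enrolled_per_group = infl$n_enrolled_per_group,
                 n_total = infl$n_total),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf(
    "Two-proportion sample size: p1=%.3f vs p2=%.3f, alpha=%.2f, power=%.2f\n",
    x$p1, x$p2, x$alpha, x$power))
  cat(sprintf("  evaluable/group %d; with %.0f%% attrition enroll %d/group (%d total)\n",
              x$n_evaluable_per_group, 100 * x$attrition,
              x$n_enrolled_per_group, x$n_total))
  invisible(x)
}

#' Per-arm TTR summary
#'
#' Summarises a per-patient TTR table ([ttr_by_patient()]) by arm: mean
#' and SD of TTR (as percentages), the count and proportion of patients
#' with effective anticoagulation (TTR above threshold; undefined TTRs
#' are excluded from the proportion), and the between-arm comparison of
#' TTR via [compare_continuous()].
#'
#' @param ttr_tbl Data frame from [ttr_by_patient()] with `arm`, `ttr`,
#'   `effective`.
#' @param arms Character pair of arm labels.
#' @return List with `by_arm` (data frame `arm`, `n`, `mean_ttr_pct`,
#'   `sd_ttr_pct`, `n_effective`, `pct_effective`), `ttr_comparison`
#'   (a `"group_comparison"`), and `effectiveness_comparison`.
#' @export
summarize_ttr_by_arm <- function(ttr_tbl, arms = c("NON_WEB", "WEB")) {
  by_arm <- do.call(rbind, lapply(arms, function(a) {
    v <- ttr_tbl$ttr[ttr_tbl$arm == a]
    e <- ttr_tbl$effective[ttr_tbl$arm == a]
    def <- !is.na(e)
    data.frame(arm = a, n = length(v),
               mean_ttr_pct = 100 * mean(v, na.rm = TRUE),
               sd_ttr_pct = 100 * stats::sd(v, na.rm = TRUE),
               n_effective = sum(e[def]),
               pct_effective = round(100 * sum(e[def]) / max(1L, sum(def)), 1),
               stringsAsFactors = FALSE)
  }))
  cmp <- compare_continuous(100 * ttr_tbl$ttr[ttr_tbl$arm == arms[1]],
                            100 * ttr_tbl$ttr[ttr_tbl$arm == arms[2]],
                            labels = arms, metric = "TTR (%)")
  eff_tab <- rbind(by_arm$n_effective,
                   vapply(arms, function(a) {
                     sum(!is.na(ttr_tbl$effective[ttr_tbl$arm == a])) -
                       by_arm$n_effective[by_arm$arm == a]
                   }, numeric(1)))
  colnames(eff_tab) <- arms
  eff_cmp <- compare_categorical(eff_tab, metric = "effective anticoagulation")
  list(by_arm = by_arm, ttr_comparison = cmp,
       effectiveness_comparison = eff_cmp)
}
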