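test_that("the normality gate routes to the t test or Mann-Whitney", {
  set.seed(5)
  x <- rnorm(200); y <- rnorm(200, 0.1)
  expect_equal(compare_continuous(x, y)$test, "T_TEST")
  z <- rexp(200)
  expect_equal(compare_continuous(x, z)$test, "MANN_WHITNEY")
  same <- rnorm(100)
  expect_gt(compare_continuous(same, same)$p_value, 0.99)
  expect_equal(compare_continuous(c(1, 2), y)$test, "INSUFFICIENT")
})

test_that("2x2 comparisons follow the expected-count gate", {
  # large balanced table -> chi-square
  g <- compare_categorical(matrix(c(1348, 1777, 1490, 1469), 2))
  expect_equal(g$test, "CHI_SQUARE")
  expect_lt(g$p_value, 0.001)
  # non-significant row
  g <- compare_categorical(matrix(c(515, 2610, 450, 2509), 2))
  expect_gt(g$p_value, 0.05)
  # zero cell -> expected count below 5 -> Fisher
  g <- compare_categorical(matrix(c(24, 3101, 0, 2959), 2))
  expect_equal(g$test, "FISHER_EXACT")
  expect_lt(g$p_value, 0.001)
  # zero column margin is degenerate
  g <- compare_categorical(matrix(c(0, 0, 3, 7), 2))
  expect_equal(g$test, "DEGENERATE")
  expect_error(compare_categorical(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("Fisher branch agrees with an exhaustive enumeration oracle", {
  set.seed(31)
  checked <- 0
  while (checked < 60) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) > 40 || any(colSums(tab) == 0)) next
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (!any(expected < 5)) next
    g <- compare_categorical(tab)
    expect_equal(g$test, "FISHER_EXACT")
    expect_equal(g$p_value, fisher_enumeration_p(tab), tolerance = 1e-7)
    checked <- checked + 1
  }
})

test_that("INR distribution tables recompute percentages from counts", {
  counts <- matrix(c(666, 515, 1348, 572, 24,
                     521, 450, 1490, 498, 0), ncol = 2,
                   dimnames = list(NULL, c("NON_WEB", "WEB")))
  tab <- inr_table_from_counts(counts)
  expect_equal(tab$pct_NON_WEB, c(21.3, 16.5, 43.1, 18.3, 0.8))
  expect_equal(tab$pct_WEB, c(17.6, 15.2, 50.4, 16.8, 0.0))
  expect_equal(unname(attr(tab, "arm_totals")), c(3125, 2959))
  # single record: 100% in its class
  one <- matrix(c(0, 0, 1, 0, 0, rep(0, 5)), ncol = 2)
  t1 <- inr_table_from_counts(one)
  expect_equal(t1[[2]][3], 1)
  expect_equal(t1[[3]][3], 100)
  # empty log: all-zero table, no tests
  t0 <- inr_table_from_counts(matrix(0L, 5, 2))
  expect_true(all(t0$test == "DEGENERATE"))
})

test_that("classification-based distribution matches direct classification", {
  registry <- data.frame(patient_id = c("A", "B"), arm = c("NON_WEB", "WEB"),
                         indications = c("ATRIAL_FIBRILLATION", "AORTIC_VALVE"),
                         stringsAsFactors = FALSE)
  inr_log <- data.frame(patient_id = c("A", "A", "B", "B", "ghost"),
                        date = c(1, 2, 1, 2, 1),
                        inr = c(1.5, 2.5, 2.1, 1.75, 2))
  expect_message(tab <- inr_distribution(inr_log, registry), "unregistered")
  expect_equal(tab$n_NON_WEB, c(1L, 0L, 1L, 0L, 0L))  # 1.5 extreme-sub, 2.5 in
  expect_equal(tab$n_WEB, c(0L, 0L, 1L, 1L, 0L))      # 2.1 supra, 1.75 in
})

test_that("event tables count each patient once per type with registry denominators", {
  registry <- data.frame(
    patient_id = sprintf("P%03d", 1:519),
    arm = c(rep("NON_WEB", 260), rep("WEB", 259)),
    stringsAsFactors = FALSE
  )
  web_ids <- registry$patient_id[registry$arm == "WEB"][1:17]
  events <- data.frame(
    patient_id = c(web_ids, web_ids[1]),  # one recurrence must not double-count
    type = "MINOR_BLEED",
    date = 10,
    stringsAsFactors = FALSE
  )
  tab <- event_summary(events, registry)
  mb <- tab[tab$type == "MINOR_BLEED", ]
  expect_equal(mb$n_WEB, 17L)
  expect_equal(mb$pct_WEB, 6.6)  # 17 / 259
  expect_equal(mb$n_NON_WEB, 0L)
  expect_error(event_summary(data.frame(patient_id = "nope", type = "DEATH",
                                        date = 1),
                             registry),
               "unknown patient")
})

test_that("Kaplan-Meier estimates match the empirical survival when uncensored", {
  registry <- data.frame(patient_id = sprintf("P%02d", 1:12),
                         arm = rep("NON_WEB", 12),
                         enroll_date = 0, exit_date = 180,
                         stringsAsFactors = FALSE)
  times <- c(5, 20, 20, 44, 90, 170)
  events <- data.frame(patient_id = registry$patient_id[seq_along(times)],
                       type = "MINOR_BLEED", date = times,
                       stringsAsFactors = FALSE)
  # give everyone an event so there is no censoring to complicate the oracle
  events <- rbind(events,
                  data.frame(patient_id = registry$patient_id[7:12],
                             type = "MINOR_BLEED", date = 179))
  cur <- cumulative_event_curves(events, registry, "MINOR_BLEED")
  all_times <- c(times, rep(179, 6))
  expect_equal(cur$fit$surv,
               empirical_survival(all_times, sort(unique(all_times))))
})

test_that("a single event steps the curve by 1/n at risk", {
  registry <- data.frame(patient_id = c("A", "B", "C", "D"),
                         arm = rep("WEB", 4),
                         enroll_date = 0, exit_date = 100,
                         stringsAsFactors = FALSE)
  events <- data.frame(patient_id = "A", type = "SEVERE_BLEED", date = 40,
                       stringsAsFactors = FALSE)
  cur <- cumulative_event_curves(events, registry, "SEVERE_BLEED")
  expect_equal(cur$fit$surv[cur$fit$time == 40], 0.75)
  expect_true(is.na(cur$p_value))  # single arm: no between-group test
})

test_that("event-free cohorts give flat curves and no test", {
  registry <- data.frame(patient_id = c("A", "B"), arm = c("WEB", "NON_WEB"),
                         enroll_date = 0, exit_date = 180,
                         stringsAsFactors = FALSE)
  cur <- cumulative_event_curves(
    data.frame(patient_id = character(0), type = character(0),
               date = numeric(0)),
    registry, "MINOR_BLEED")
  expect_true(all(cur$fit$surv == 1))
  expect_true(is.na(cur$p_value))
})

test_that("log-rank separates arms more than shuffled labels", {
  set.seed(88)
  n <- 120
  registry <- data.frame(patient_id = sprintf("P%03d", 1:(2 * n)),
                         arm = rep(c("NON_WEB", "WEB"), each = n),
                         enroll_date = 0, exit_date = 180,
                         stringsAsFactors = FALSE)
  # non-web events earlier and more frequent
  t_non <- rexp(n, 1 / 120)
  t_web <- rexp(n, 1 / 400)
  mk <- function(ids, tm) {
    keep <- tm < 180
    data.frame(patient_id = ids[keep], type = "MINOR_BLEED",
               date = round(tm[keep]) + 1, stringsAsFactors = FALSE)
  }
  events <- rbind(mk(registry$patient_id[1:n], t_non),
                  mk(registry$patient_id[(n + 1):(2 * n)], t_web))
  p_actual <- cumulative_event_curves(events, registry, "MINOR_BLEED")$p_value
  reg_shuffled <- registry
  reg_shuffled$arm <- sample(registry$arm)
  p_shuffled <- cumulative_event_curves(events, reg_shuffled, "MINOR_BLEED")$p_value
  expect_lt(p_actual, 0.05)
  expect_lt(p_actual, p_shuffled)
})

test_that("sample-size arithmetic inflates for attrition correctly", {
  infl <- enrollment_for_attrition(206, 0.20)
  expect_equal(infl$n_enrolled_per_group, 258)
  expect_equal(infl$n_total, 516)
  expect_equal(enrollment_for_attrition(206, 0)$n_enrolled_per_group, 206)
  expect_error(enrollment_for_attrition(100, 1), "attrition")
})

test_that("two-proportion sample size matches the normal-approximation form", {
  res <- sample_size_two_proportions(0.731, 0.66, alpha = 0.05, power = 0.80,
                                     attrition = 0.20)
  # cross-check against the unpooled reference implementation in stats
  ref <- stats::power.prop.test(p1 = 0.731, p2 = 0.66, power = 0.80)$n
  expect_equal(res$n_evaluable_per_group, ceiling(ref), tolerance = 0.03)
  expect_equal(res$n_enrolled_per_group,
               ceiling(res$n_evaluable_per_group / 0.8))
  expect_equal(res$n_total, 2 * res$n_enrolled_per_group)
  expect_error(sample_size_two_proportions(0.6, 0.7), "p2 < p1")
})

test_that("arm TTR summaries recompute proportions from the flags", {
  tt <- data.frame(arm = rep(c("NON_WEB", "WEB"), each = 10),
                   ttr = c(rep(0.5, 6), rep(0.9, 4), rep(0.9, 8), rep(0.5, 2)),
                   effective = c(rep(FALSE, 6), rep(TRUE, 4),
                                 rep(TRUE, 8), rep(FALSE, 2)))
  s <- summarize_ttr_by_arm(tt)
  expect_equal(s$by_arm$pct_effective, c(40, 80))
  expect_equal(s$by_arm$n, c(10, 10))
})
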