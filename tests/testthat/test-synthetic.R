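test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- simulation_config(n_per_arm = c(WEB = 8, NON_WEB = 8), seed = 13)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$registry, b$registry)
  expect_identical(a$inr_log, b$inr_log)
  expect_identical(a$events, b$events)
})

test_that("changing the seed changes trajectories but not schemas", {
  a <- simulate_cohort(simulation_config(n_per_arm = c(WEB = 6, NON_WEB = 6), seed = 1))
  b <- simulate_cohort(simulation_config(n_per_arm = c(WEB = 6, NON_WEB = 6), seed = 2))
  expect_identical(names(a$inr_log), names(b$inr_log))
  expect_identical(names(a$registry), names(b$registry))
  expect_false(identical(a$inr_log$inr, b$inr_log$inr))
})

test_that("the registry has one row per requested patient", {
  coh <- simulate_cohort(simulation_config(n_per_arm = c(WEB = 10, NON_WEB = 9)))
  expect_equal(nrow(coh$registry), 19L)
  expect_equal(sum(coh$registry$arm == "WEB"), 10L)
  expect_false(anyDuplicated(coh$registry$patient_id) > 0)
})

test_that("noise-free fully adherent patients converge monotonically from below", {
  cfg <- deterministic_config()
  p <- simulate_patient(cfg, "WEB", seed = 5)
  s <- p$sensitivity
  dose <- p$dose_history$dose[1]
  ss <- 1 + s * dose
  path <- p$true_inr_path
  # dose never changes (steady state sits inside the no-change zone)
  expect_true(all(p$dose_history$dose == dose))
  # the gap to steady state shrinks monotonically and closes
  gaps <- abs(path - ss)
  expect_true(all(diff(gaps) <= 1e-9))
  expect_lt(gaps[length(gaps)], 0.01)
  expect_true(all(diff(path) >= -1e-9))  # approaches from below
})

test_that("TTR on the dense true path recovers the generative in-range fraction", {
  cfg <- deterministic_config()
  for (sd in c(3, 8)) {
    p <- simulate_patient(cfg, "NON_WEB", seed = sd)
    rng <- p$range
    path <- p$true_inr_path
    truth <- mean(path >= rng[["lower"]] & path <= rng[["upper"]])
    r <- rosendaal_ttr(seq_along(path) - 1, path, rng)
    expect_equal(r$ttr, truth, tolerance = 0.02)
  }
})

test_that("without visit delays every surviving patient is seen at least six times", {
  cfg <- simulation_config(
    n_per_arm = c(WEB = 15, NON_WEB = 15), seed = 3,
    visit_delay_lognorm_sigma_by_arm = c(WEB = 0, NON_WEB = 0),
    visit_gap_cap_days = 28
  )
  coh <- simulate_cohort(cfg)
  alive <- coh$registry$patient_id[!coh$registry$died]
  n_meas <- table(factor(coh$inr_log$patient_id, levels = alive))
  expect_true(all(n_meas >= 6))
})

test_that("measurements and events stay inside the follow-up window", {
  coh <- simulate_cohort(simulation_config(n_per_arm = c(WEB = 30, NON_WEB = 30),
                                           seed = 21))
  for (p in coh$trajectories) {
    expect_true(all(p$measurements$day >= 1 & p$measurements$day <= p$censor_day))
    if (nrow(p$events) > 0) {
      expect_true(all(p$events$day <= p$censor_day))
      deaths <- which(p$events$type == "DEATH")
      expect_lte(length(deaths), 1L)
      if (length(deaths) == 1L) {
        expect_equal(p$events$day[deaths], p$censor_day)  # death is terminal
        expect_true(p$died)
      }
    }
  }
})

test_that("the web arm shows better INR control at the default calibration", {
  coh <- simulate_cohort(simulation_config(n_per_arm = c(WEB = 150, NON_WEB = 150),
                                           seed = 4))
  tt <- ttr_by_patient(coh$inr_log, coh$registry)
  s <- summarize_ttr_by_arm(tt)
  m <- s$by_arm
  expect_gt(m$mean_ttr_pct[m$arm == "WEB"], m$mean_ttr_pct[m$arm == "NON_WEB"])
  dist <- inr_distribution(coh$inr_log, coh$registry)
  ther <- dist[dist$class == "THERAPEUTIC", ]
  expect_gt(ther$pct_WEB, ther$pct_NON_WEB)
})

test_that("raising the supratherapeutic hazard slope raises bleeding counts", {
  # common random numbers: identical seeds, only the slope differs, and
  # deaths are disabled so censoring cannot shorten follow-up
  base <- list(n_per_arm = c(WEB = 100, NON_WEB = 100), seed = 8,
               death_prob_severe = 0)
  lo <- simulate_cohort(do.call(simulation_config,
                                c(base, hazard_slope_supra = 2)))
  hi <- simulate_cohort(do.call(simulation_config,
                                c(base, hazard_slope_supra = 8)))
  n_lo <- sum(lo$events$type == "MINOR_BLEED")
  n_hi <- sum(hi$events$type == "MINOR_BLEED")
  expect_gt(n_hi, n_lo)
})

test_that("invalid configurations fail before any sampling", {
  expect_error(simulation_config(approach_rate = 1.5), "approach_rate")
  expect_error(simulation_config(adherence_mean_by_arm = c(WEB = 1.2, NON_WEB = 0.9)),
               "\\[0, 1\\]")
  expect_error(simulation_config(hazard_base_bleed_minor = -1), "finite")
  expect_error(simulation_config(indication_probs = c(VTE = 0.5)), "probability")
  expect_error(simulation_config(n_per_arm = c(WEB = 5)), "NON_WEB")
})
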