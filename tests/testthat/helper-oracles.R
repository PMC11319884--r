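# Independent oracles used to cross-check the analytic implementations.

# Time-in-range by brute-force discretization: chop every segment into
# `steps` equal slices and classify each slice's midpoint INR.
ttr_discretized <- function(dates, inr, range, steps = 10000L) {
  t <- as.numeric(dates)
  lo <- range[[1L]]
  hi <- range[[2L]]
  below <- 0; inside <- 0; above <- 0
  for (k in seq_len(length(t) - 1L)) {
    d <- t[k + 1L] - t[k]
    if (d <= 0) next
    u <- (seq_len(steps) - 0.5) / steps
    v <- inr[k] + u * (inr[k + 1L] - inr[k])
    below <- below + d * mean(v < lo)
    above <- above + d * mean(v > hi)
    inside <- inside + d * mean(v >= lo & v <= hi)
  }
  list(days_below = below, days_in = inside, days_above = above,
       ttr = inside / (below + inside + above))
}

# Two-sided Fisher exact p by enumeration over all tables with the
# observed margins (probabilities via lchoose, summed for tables no more
# probable than the observed one).
fisher_enumeration_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[support == tab[1, 1]]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Empirical survival function (no censoring): S(t) = P(T > t).
empirical_survival <- function(times, at) {
  vapply(at, function(t) mean(times > t), numeric(1))
}

# random INR series for property tests
random_inr_series <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:30, 1)
  dates <- cumsum(c(0, sample(1:21, n - 1, replace = TRUE)))
  inr <- round(runif(n, 0.8, 6.0), 2)
  list(dates = dates, inr = inr)
}

# a fully deterministic simulation configuration (no noise, no drift,
# full adherence, fixed indication and sensitivity)
deterministic_config <- function(...) {
  simulation_config(
    n_per_arm = c(WEB = 2L, NON_WEB = 2L),
    sensitivity_cv = 0, sensitivity_walk_sd = 0, sensitivity_jump_prob = 0,
    process_sd = 0, measurement_cv = 0,
    adherence_mean_by_arm = c(WEB = 1, NON_WEB = 1),
    visit_delay_lognorm_sigma_by_arm = c(WEB = 0, NON_WEB = 0),
    hazard_base_bleed_minor = 0, hazard_base_bleed_severe = 0,
    hazard_base_thrombo = 0,
    indication_probs = c(ATRIAL_FIBRILLATION = 1),
    init_inr_frac = c(0.8, 0.8), init_dose_sd = 0,
    ...
  )
}
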