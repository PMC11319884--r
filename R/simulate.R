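# Virtual-patient cohort simulator.
#
# Generative model, per patient:
#   * per-patient dose sensitivity s ~ LogNormal (median, CV configurable);
#     steady-state INR for a taken dose d is INR_ss(d) = 1 + s * d.
#   * the sensitivity drifts day to day as a lognormal random walk
#     (log s[t+1] = log s[t] + Normal(0, sensitivity_walk_sd)), and with a
#     small daily probability takes a lognormal jump (starting or stopping
#     an interacting drug, intercurrent illness): warfarin response shifts
#     over time, and a drifted patient stays out of range until a visit
#     corrects the dose -- this is what makes monitoring frequency and
#     delay matter.
#   * daily dynamics (first-order approach to steady state, capturing
#     warfarin's delayed response):
#       INR[t+1] = INR[t] + approach_rate * (INR_ss(d_eff[t]) - INR[t])
#                  + Normal(0, process_sd)
#     with d_eff = prescribed dose on adherent days, 0 on missed days and
#     during holds. True INR floored at 0.8 (physiological baseline).
#   * adherence: each patient has a long-run intake fraction a ~ Beta
#     matched to the arm mean; missed doses arrive as multi-day spells
#     (a two-state process: spells start at rate (1-a)/(a*L) per day and
#     last Geometric(mean L) days), since patients forget or stop for
#     stretches rather than on isolated random days. L = 1 recovers
#     near-independent daily misses.
#   * observed INR = true INR * exp(Normal(0, measurement_cv)).
#   * visits follow the monitoring ladder (schedule_engine), stretched by
#     a LogNormal(0, sigma_arm) multiplicative delay (the web arm's sigma
#     is ~0); hold rechecks happen the next day, undelayed; no gap exceeds
#     `visit_gap_cap_days` (appointment reminders exist in both arms).
#   * doses follow the titration rules (dose_engine) on observed INRs.
#   * daily event hazards: bleeding scales with supratherapeutic excess,
#     thromboembolism with subtherapeutic excess,
#       h_bleed  = base * exp(slope_supra * max(0, INR - upper))
#       h_thromb = base * exp(slope_sub   * max(0, lower - INR));
#     a severe bleed or thromboembolic event is fatal with probability
#     `death_prob_severe`; death censors the trajectory.
#
# The two arms differ only through monitoring delay and adherence --
# the hypothesised mechanisms of app-supported management -- never
# through different dose rules.

.minor_subtypes <- c("epistaxis", "gingival_oral_bleeding", "skin_ecchymosis",
                     "fundus_hemorrhage", "menorrhagia", "hematuria")
.severe_subtypes <- c("gastrointestinal_bleeding", "intracranial_hemorrhage")
.thrombo_subtypes <- c("TIA", "VTE", "valve_thrombosis", "ischemic_stroke")

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()] /
#' [simulate_patient()]. Defaults are a documented calibration emulating a
#' six-month two-arm warfarin management comparison (~260 patients per
#' arm, ~12 INR checks per patient, arm mean TTR near 82% (WEB) vs 72%
#' (NON_WEB), minor-bleeding incidence near 7% vs 12%).
#'
#' @param n_per_arm Named integer vector `c(WEB = ..., NON_WEB = ...)`.
#' @param follow_up_days Follow-up horizon in days.
#' @param sensitivity_median Median steady-state INR gain per tablet/day.
#' @param sensitivity_cv Coefficient of variation of the sensitivity
#'   between patients.
#' @param sensitivity_walk_sd Daily SD of the within-patient
#'   log-sensitivity random walk (0 freezes each patient's sensitivity).
#' @param sensitivity_jump_prob Daily probability of an abrupt
#'   log-sensitivity jump (interaction/illness episodes).
#' @param sensitivity_jump_sd SD of the jump size on the log scale.
#' @param approach_rate Daily fractional approach to steady state (1/days).
#' @param process_sd SD of daily biological INR noise (INR units).
#' @param measurement_cv Multiplicative lognormal assay error (CV).
#' @param adherence_mean_by_arm Named vector of mean daily intake
#'   probability per arm.
#' @param adherence_kappa Beta concentration for between-patient adherence
#'   spread.
#' @param adherence_spell_days Mean length (days) of a missed-dose spell;
#'   1 approximates independent daily misses.
#' @param visit_delay_lognorm_sigma_by_arm Named vector; sigma of the
#'   multiplicative lognormal visit delay per arm.
#' @param visit_gap_cap_days Hard cap on any realised visit gap (days).
#' @param hazard_base_bleed_minor,hazard_base_bleed_severe,hazard_base_thrombo
#'   Baseline daily event hazards.
#' @param hazard_slope_supra,hazard_slope_sub Log-hazard slope per INR
#'   unit of excess above/below the range.
#' @param death_prob_severe Probability that a severe bleed or
#'   thromboembolic event is fatal.
#' @param indication_probs Named probability vector over
#'   [indication_codes()] (must sum to 1).
#' @param init_inr_frac Length-2 range; the day-0 true INR is
#'   `1 + s * dose0 * U(init_inr_frac)` (patients leave hospital partially
#'   titrated).
#' @param init_dose_sd Lognormal SD of the initial-dose titration error.
#' @param seed Master seed (integer).
#' @return Object of class `"simulation_config"` (a validated list).
#' @export
simulation_config <- function(
    n_per_arm = c(WEB = 260L, NON_WEB = 259L),
    follow_up_days = 180L,
    sensitivity_median = 0.55,
    sensitivity_cv = 0.30,
    sensitivity_walk_sd = 0.015,
    sensitivity_jump_prob = 0.006,
    sensitivity_jump_sd = 0.35,
    approach_rate = 0.25,
    process_sd = 0.05,
    measurement_cv = 0.025,
    adherence_mean_by_arm = c(WEB = 0.985, NON_WEB = 0.88),
    adherence_kappa = 8,
    adherence_spell_days = 4,
    visit_delay_lognorm_sigma_by_arm = c(WEB = 0.01, NON_WEB = 1.3),
    visit_gap_cap_days = 42L,
    hazard_base_bleed_minor = 1.75e-4,
    hazard_base_bleed_severe = 1.3e-6,
    hazard_base_thrombo = 2e-5,
    hazard_slope_supra = 8,
    hazard_slope_sub = 5,
    death_prob_severe = 0.15,
    indication_probs = c(AORTIC_VALVE = 0.30, MITRAL_VALVE = 0.50,
                         TRICUSPID_VALVE = 0.17,
                         ATRIAL_FIBRILLATION = 0.014, VTE = 0.016),
    init_inr_frac = c(0.9, 1.05),
    init_dose_sd = 0.08,
    seed = 1L) {
  cfg <- list(n_per_arm = n_per_arm, follow_up_days = as.integer(follow_up_days),
              sensitivity_median = sensitivity_median,
              sensitivity_cv = sensitivity_cv,
              sensitivity_walk_sd = sensitivity_walk_sd,
              sensitivity_jump_prob = sensitivity_jump_prob,
              sensitivity_jump_sd = sensitivity_jump_sd,
              approach_rate = approach_rate,
              process_sd = process_sd, measurement_cv = measurement_cv,
              adherence_mean_by_arm = adherence_mean_by_arm,
              adherence_kappa = adherence_kappa,
              adherence_spell_days = adherence_spell_days,
              visit_delay_lognorm_sigma_by_arm = visit_delay_lognorm_sigma_by_arm,
              visit_gap_cap_days = as.integer(visit_gap_cap_days),
              hazard_base_bleed_minor = hazard_base_bleed_minor,
              hazard_base_bleed_severe = hazard_base_bleed_severe,
              hazard_base_thrombo = hazard_base_thrombo,
              hazard_slope_supra = hazard_slope_supra,
              hazard_slope_sub = hazard_slope_sub,
              death_prob_severe = death_prob_severe,
              indication_probs = indication_probs,
              init_inr_frac = init_inr_frac, init_dose_sd = init_dose_sd,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  arms <- c("WEB", "NON_WEB")
  if (!all(arms %in% names(cfg$n_per_arm)) || any(cfg$n_per_arm < 0)) {
    stop("`n_per_arm` must be a nonnegative vector named WEB and NON_WEB",
         call. = FALSE)
  }
  if (cfg$follow_up_days < 1) stop("`follow_up_days` must be >= 1", call. = FALSE)
  rates <- c(cfg$hazard_base_bleed_minor, cfg$hazard_base_bleed_severe,
             cfg$hazard_base_thrombo, cfg$hazard_slope_supra,
             cfg$hazard_slope_sub, cfg$approach_rate, cfg$process_sd,
             cfg$measurement_cv, cfg$sensitivity_cv, cfg$sensitivity_median,
             cfg$sensitivity_walk_sd, cfg$sensitivity_jump_sd)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates, slopes and noise scales must be finite and >= 0", call. = FALSE)
  }
  if (cfg$approach_rate > 1) stop("`approach_rate` must be in [0, 1]", call. = FALSE)
  if (cfg$adherence_spell_days < 1) {
    stop("`adherence_spell_days` must be >= 1", call. = FALSE)
  }
  fr <- c(cfg$adherence_mean_by_arm, cfg$death_prob_severe,
          cfg$sensitivity_jump_prob)
  if (any(fr < 0 | fr > 1)) {
    stop("adherence means and death probability must lie in [0, 1]", call. = FALSE)
  }
  if (!all(arms %in% names(cfg$adherence_mean_by_arm)) ||
      !all(arms %in% names(cfg$visit_delay_lognorm_sigma_by_arm))) {
    stop("per-arm parameters must be named WEB and NON_WEB", call. = FALSE)
  }
  if (any(cfg$visit_delay_lognorm_sigma_by_arm < 0)) {
    stop("visit delay sigmas must be >= 0", call. = FALSE)
  }
  p <- cfg$indication_probs
  if (!all(names(p) %in% indication_codes()) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8) {
    stop("`indication_probs` must be a probability vector over indication_codes()",
         call. = FALSE)
  }
  if (length(cfg$init_inr_frac) != 2L || any(cfg$init_inr_frac <= 0) ||
      diff(cfg$init_inr_frac) < 0) {
    stop("`init_inr_frac` must be an increasing positive pair", call. = FALSE)
  }
  invisible(cfg)
}

quantize_quarter <- function(d) round(d / 0.25) * 0.25

#' Simulate one patient trajectory
#'
#' Runs the daily generative model (see [simulation_config()]) for a
#' single patient, driving measurement timing through the monitoring
#' ladder and dosing through the titration rules.
#'
#' @param config A [simulation_config()].
#' @param arm `"WEB"` or `"NON_WEB"`.
#' @param patient_id Identifier string.
#' @param seed Integer seed for this patient's private RNG stream.
#' @param ranges Indication-to-range table (default
#'   [default_target_ranges()]).
#' @return Object of class `"patient_trajectory"`: list with `patient_id`,
#'   `arm`, `indications`, `range`, `sensitivity`, `adherence`,
#'   `true_inr_path` (daily true INR, day 0 .. censor day),
#'   `measurements` (data frame `day`, `inr`, `dose_in_effect`),
#'   `dose_history` (data frame `day`, `dose`), `events` (data frame
#'   `type`, `subtype`, `day`), `censor_day`, `died`.
#' @export
simulate_patient <- function(config, arm = c("WEB", "NON_WEB"),
                             patient_id = "P1", seed = 1L,
                             ranges = default_target_ranges()) {
  validate_simulation_config(config)
  arm <- match.arg(arm)
  set.seed(as.integer(seed))
  T_end <- config$follow_up_days

  ind <- sample(names(config$indication_probs), 1L,
                prob = config$indication_probs)
  rng <- resolve_target_range(ind, ranges)
  lo <- rng[["lower"]]; hi <- rng[["upper"]]

  sdlog <- sqrt(log(1 + config$sensitivity_cv^2))
  s <- stats::rlnorm(1, meanlog = log(config$sensitivity_median), sdlog = sdlog)

  a_mean <- config$adherence_mean_by_arm[[arm]]
  kap <- config$adherence_kappa
  adherence <- if (a_mean >= 1) 1 else if (a_mean <= 0) 0 else
    stats::rbeta(1, a_mean * kap, (1 - a_mean) * kap)

  sig_delay <- config$visit_delay_lognorm_sigma_by_arm[[arm]]
  gap_cap <- config$visit_gap_cap_days

  # discharge state: dose titrated in hospital with some residual error
  mid <- (lo + hi) / 2
  dose0 <- quantize_quarter(max(0.25, (mid - 1) / s *
                                  stats::rlnorm(1, 0, config$init_dose_sd)))
  true <- max(0.8, 1 + s * dose0 * stats::runif(1, config$init_inr_frac[1],
                                                config$init_inr_frac[2]))

  # pre-drawn daily randomness (keeps the stream layout fixed)
  proc <- stats::rnorm(T_end, 0, config$process_sd)
  s_innov <- stats::rnorm(T_end, 0, config$sensitivity_walk_sd) +
    (stats::runif(T_end) < config$sensitivity_jump_prob) *
      stats::rnorm(T_end, 0, config$sensitivity_jump_sd)
  s_path <- s * exp(cumsum(s_innov))
  adh_u <- stats::runif(T_end)
  spell_u <- stats::runif(T_end)
  ev_u <- matrix(stats::runif(3L * T_end), ncol = 3L)
  death_u <- stats::runif(T_end)

  # missed-dose spells: start rate chosen so the long-run miss fraction
  # equals 1 - adherence; lengths Geometric with mean adherence_spell_days
  L <- config$adherence_spell_days
  spell_start_p <- if (adherence >= 1) 0 else (1 - adherence) / (adherence * L)
  taken <- rep(TRUE, T_end)
  miss_left <- 0L
  for (t in seq_len(T_end)) {
    if (miss_left > 0L) {
      taken[t] <- FALSE
      miss_left <- miss_left - 1L
    } else if (adh_u[t] < spell_start_p) {
      taken[t] <- FALSE
      # geometric (support 1, 2, ...) by inversion, mean L
      miss_left <- as.integer(floor(log(spell_u[t]) / log(1 - 1 / L)))
    }
  }

  state <- dose_state(dose0)
  sched <- monitoring_state()
  delay <- function() max(1, exp(stats::rnorm(1, 0, sig_delay)))  # late, never early
  next_visit <- min(gap_cap, max(1L, as.integer(round(7 * delay()))))

  path <- numeric(T_end + 1L)
  path[1L] <- true
  meas_day <- integer(0); meas_inr <- numeric(0); meas_dose <- numeric(0)
  dh_day <- 0L; dh_dose <- dose0
  ev_type <- character(0); ev_sub <- character(0); ev_day <- integer(0)
  censor_day <- T_end
  died <- FALSE

  for (t in seq_len(T_end)) {
    d_eff <- if (state$holding) 0 else if (taken[t]) state$dose else 0
    true <- true + config$approach_rate * (1 + s_path[t] * d_eff - true) + proc[t]
    true <- max(true, 0.8)
    path[t + 1L] <- true

    exc_sup <- max(0, true - hi)
    exc_sub <- max(0, lo - true)
    h_minor <- config$hazard_base_bleed_minor * exp(config$hazard_slope_supra * exc_sup)
    h_sev <- config$hazard_base_bleed_severe * exp(config$hazard_slope_supra * exc_sup)
    h_thr <- config$hazard_base_thrombo * exp(config$hazard_slope_sub * exc_sub)
    if (ev_u[t, 1L] < 1 - exp(-h_minor)) {
      ev_type <- c(ev_type, "MINOR_BLEED")
      ev_sub <- c(ev_sub, sample(.minor_subtypes, 1L))
      ev_day <- c(ev_day, t)
    }
    if (ev_u[t, 2L] < 1 - exp(-h_sev)) {
      ev_type <- c(ev_type, "SEVERE_BLEED")
      ev_sub <- c(ev_sub, sample(.severe_subtypes, 1L))
      ev_day <- c(ev_day, t)
      if (death_u[t] < config$death_prob_severe) died <- TRUE
    }
    if (ev_u[t, 3L] < 1 - exp(-h_thr)) {
      ev_type <- c(ev_type, "THROMBOEMBOLIC")
      ev_sub <- c(ev_sub, sample(.thrombo_subtypes, 1L))
      ev_day <- c(ev_day, t)
      if (death_u[t] < config$death_prob_severe) died <- TRUE
    }
    if (died) {
      ev_type <- c(ev_type, "DEATH")
      ev_sub <- c(ev_sub, "all_cause")
      ev_day <- c(ev_day, t)
      censor_day <- t
      break
    }

    if (t == next_visit) {
      obs <- round(true * exp(stats::rnorm(1, 0, config$measurement_cv)), 2)
      obs <- max(obs, 0.5)
      meas_day <- c(meas_day, t)
      meas_inr <- c(meas_inr, obs)
      meas_dose <- c(meas_dose, if (state$holding) 0 else state$dose)
      rec <- recommend_dose(obs, rng, state)
      state <- apply_recommendation(state, rec, date = t)
      if (rec$action %in% c("HOLD_ONE_DAY", "CONTINUE_HOLD")) {
        next_visit <- t + 1L
      } else {
        in_r <- obs >= lo && obs <= hi
        sched <- next_interval(sched, in_r, rec$action != "NO_CHANGE")
        gap <- min(gap_cap, max(1L, as.integer(round(
          sched$interval_weeks * 7 * delay()))))
        next_visit <- t + gap
      }
      dh_day <- c(dh_day, t)
      dh_dose <- c(dh_dose, if (state$holding) 0 else state$dose)
    }
  }

  structure(list(
    patient_id = patient_id, arm = arm, indications = ind, range = rng,
    sensitivity = s, adherence = adherence,
    true_inr_path = path[seq_len(censor_day + 1L)],
    measurements = data.frame(day = meas_day, inr = meas_inr,
                              dose_in_effect = meas_dose),
    dose_history = data.frame(day = dh_day, dose = dh_dose),
    events = data.frame(type = ev_type, subtype = ev_sub, day = ev_day,
                        stringsAsFactors = FALSE),
    censor_day = censor_day, died = died
  ), class = "patient_trajectory")
}

#' Simulate a two-arm cohort
#'
#' Generates the full cohort -- registry, INR log and event log -- with
#' independent per-patient RNG substreams derived from the master seed,
#' in the same tabular schemas the file readers produce
#' ([read_inr_log()] etc.).
#'
#' @param config A [simulation_config()].
#' @param ranges Indication-to-range table.
#' @param enroll_date Common enrollment `Date` used to place day numbers
#'   on the calendar.
#' @return Object of class `"cohort"`: list with data frames `registry`
#'   (`patient_id`, `arm`, `indications`, `enroll_date`, `exit_date`,
#'   `died`), `inr_log` (`patient_id`, `date`, `inr`, `dose_tablets`),
#'   `events` (`patient_id`, `type`, `subtype`, `date`), the list
#'   `trajectories`, and the `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(simulation_config(n_per_arm = c(WEB = 3, NON_WEB = 3)))
#' nrow(coh$registry)
simulate_cohort <- function(config = simulation_config(),
                            ranges = default_target_ranges(),
                            enroll_date = as.Date("2020-01-01")) {
  validate_simulation_config(config)
  n_web <- as.integer(config$n_per_arm[["WEB"]])
  n_non <- as.integer(config$n_per_arm[["NON_WEB"]])
  n <- n_web + n_non
  arms <- c(rep("WEB", n_web), rep("NON_WEB", n_non))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("P%04d", seq_len(n))

  traj <- vector("list", n)
  for (i in seq_len(n)) {
    traj[[i]] <- simulate_patient(config, arms[i], ids[i], seeds[i], ranges)
  }

  registry <- data.frame(
    patient_id = ids, arm = arms,
    indications = vapply(traj, function(p) paste(p$indications, collapse = ";"),
                         character(1)),
    enroll_date = enroll_date,
    exit_date = enroll_date + vapply(traj, function(p) p$censor_day, numeric(1)),
    died = vapply(traj, function(p) p$died, logical(1)),
    stringsAsFactors = FALSE
  )
  inr_log <- do.call(rbind, lapply(traj, function(p) {
    if (nrow(p$measurements) == 0L) return(NULL)
    data.frame(patient_id = p$patient_id,
               date = enroll_date + p$measurements$day,
               inr = p$measurements$inr,
               dose_tablets = p$measurements$dose_in_effect,
               stringsAsFactors = FALSE)
  }))
  events <- do.call(rbind, lapply(traj, function(p) {
    if (nrow(p$events) == 0L) return(NULL)
    data.frame(patient_id = p$patient_id, type = p$events$type,
               subtype = p$events$subtype,
               date = enroll_date + p$events$day,
               stringsAsFactors = FALSE)
  }))
  if (is.null(inr_log)) {
    inr_log <- data.frame(patient_id = character(0), date = as.Date(character(0)),
                          inr = numeric(0), dose_tablets = numeric(0))
  }
  if (is.null(events)) {
    events <- data.frame(patient_id = character(0), type = character(0),
                         subtype = character(0), date = as.Date(character(0)))
  }
  structure(list(registry = registry, inr_log = inr_log, events = events,
                 trajectories = traj, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d patients (%d WEB / %d NON_WEB), %d INR records, %d events\n",
              nrow(x$registry), sum(x$registry$arm == "WEB"),
              sum(x$registry$arm == "NON_WEB"), nrow(x$inr_log),
              nrow(x$events)))
  invisible(x)
}
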