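# anticoagr

Quantitative tools for warfarin anticoagulation management and for
evaluating management programmes against each other.

Warfarin has a narrow therapeutic window. Its anticoagulant intensity is
measured by the INR (international normalized ratio), which must be kept
inside an indication-specific target interval — e.g. 2–3 for atrial
fibrillation, narrower intervals after valve surgery — through regular
blood tests and small dose adjustments. The standard quality metric is
the **time in therapeutic range (TTR)** by Rosendaal linear
interpolation: between consecutive INR measurements at times *t₁ < t₂*
with values *i₁, i₂*, the INR is assumed linear in time, person-time is
split analytically at the crossing points of the range limits, and

> TTR = (days with interpolated INR ∈ [lower, upper]) / (total
> interpolated days).

TTR > 65% is the conventional benchmark for effective anticoagulation.

The package provides, for clinical-pharmacology and biostatistics users:

* **INR domain** — indication → target-range resolution (highest range
  wins for combined indications) and the five-level INR classification
  (extreme subtherapeutic < lower−0.2, subtherapeutic, therapeutic,
  supratherapeutic ≤ 4.5, extreme supratherapeutic > 4.5).
* **TTR** — exact Rosendaal person-time decomposition with an optional
  interpolation gap cap, and the strict TTR > 65% effectiveness flag.
* **Dose engine** — the six-rule titration protocol: no change within
  ±0.2 of the limits; ±0.25 tablets outside; INR > 3 → stop one day and
  recheck; resume at the pre-hold dose − 0.25 once INR ≤ 3.
* **Schedule engine** — the monitoring-interval ladder: weekly at the
  start, +1 week after two consecutive in-range results, capped at one
  month, reset to weekly on any dose change.
* **Synthetic cohort** — a seeded virtual-patient generator (daily INR
  dynamics with drifting dose sensitivity, spell-structured adherence,
  assay noise, protocol-driven visits and dosing, INR-dependent bleeding
  and thromboembolic hazards) emulating a two-arm comparison of
  app-supported ("web") versus conventional outpatient management.
* **Cohort analysis** — normality-gated t/Mann-Whitney comparisons,
  χ²/Fisher 2×2 tables, INR-distribution and clinical-event tables,
  Kaplan-Meier time-to-first-event curves with log-rank tests, and
  two-proportion sample size with attrition inflation.

## Worked example

```r
library(anticoagr)

# TTR for one patient on range (2, 3)
rosendaal_ttr(c(0, 7, 21, 35), c(1.6, 2.4, 3.4, 2.6), target_range(2, 3))
#> Rosendaal TTR: 54.0%  (below 3.5 d, in 18.9 d, above 12.6 d over 3 pairs)

# dose advice for a high INR
recommend_dose(3.4, target_range(2, 3), dose_state(1.25))
#> HOLD_ONE_DAY -> 0.00 tablets/day (recheck in 1 day)

# a full two-arm synthetic cohort and its comparison
coh <- simulate_cohort(simulation_config(seed = 42))
coh
#> Simulated cohort: 519 patients (260 WEB / 259 NON_WEB), 5309 INR records, 352 events

tt <- ttr_by_patient(coh$inr_log, coh$registry)
summarize_ttr_by_arm(tt)$by_arm
#>       arm   n mean_ttr_pct sd_ttr_pct n_effective pct_effective
#> 1 NON_WEB 259     69.04369   26.53202         153          59.1
#> 2     WEB 260     82.26764   22.84123         203          78.1

event_summary(coh$events, coh$registry)[1, ]
#>          type n_NON_WEB pct_NON_WEB n_WEB pct_WEB       test   p_value
#> 1 MINOR_BLEED        33        12.7    23     8.8 CHI_SQUARE 0.1975371
```

The simulated app-supported arm keeps a mean TTR near 82% against ~70%
under conventional management, with fewer minor bleeding events — the
separation is produced entirely by faster visit turnaround and better
adherence, never by different dosing rules.

A command-line front end over the same functions ships in
`inst/cli/anticoag.R` (subcommands `simulate`, `ttr`, `dose`,
`schedule`, `analyze`).

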