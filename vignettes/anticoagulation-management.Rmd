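---
title: "Models and methods behind anticoagr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind anticoagr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anticoagr)
```

This vignette records the models, numerical choices and design decisions
behind the package, in the spirit of a methods appendix. Nothing here is
an empirical claim beyond what the package's own tests and
`scripts/acceptance.R` compute.

## The INR domain

Warfarin intensity is tracked by the INR, a dimensionless prothrombin
ratio. Each anticoagulation indication maps to one therapeutic interval;
the built-in table (aortic valve 1.5–2, mitral 1.7–2.5, tricuspid 2–2.5,
atrial fibrillation 2–3, venous thromboembolism 2–3) reflects the
practice of centres that run deliberately lower valve targets than some
guidelines; it ships as a versioned JSON config precisely so deployments
can substitute their own. For combined indications the most intense
range governs: maximal upper limit, ties broken by maximal lower limit.
The tie-break is our own plumbing — only the "higher range wins"
principle is clinically established.

The five-level classification partitions the positive axis:
`EXTREME_SUB` below lower − 0.2, `SUB` up to (exclusive) the lower
limit, `THERAPEUTIC` with both limits inclusive, `SUPRA` up to 4.5, and
`EXTREME_SUPRA` beyond. A boundary subtlety: one natural reading of the
supratherapeutic band starts it at upper + 0.2, which would leave
(upper, upper + 0.2] unclassified. We treat `SUPRA` as starting
immediately above the upper limit, keeping the five classes a strict
partition (the sub side shows the 0.2 margin lives *inside* the
adjacent class, not outside the partition); the switch
`upper_margin_therapeutic = TRUE` exposes the alternative reading, which
aligns the therapeutic class with the dose engine's no-change zone.

## Rosendaal TTR

Between consecutive measurements the INR is modelled as linear in time;
each segment's duration is split analytically at the crossing times of
the range limits, in continuous days — rounding crossing times to whole
days changes TTR by more than 1% on short series, so we never round.
Each segment contributes the half-open interval [t₁, t₂), so
consecutive segments cannot double-count a day, and the decomposition
below + in + above reproduces the interpolated span exactly (a test
asserts this to 1e-12). Correctness is checked against an independent
10,000-step discretization oracle to an absolute 1e-3 on random series.

Design choices:

* **Gap cap** — the classical formulation interpolates across any gap;
  `max_gap_days = Inf` is therefore the default, with a configurable cap
  (56 days is common in registry work) off by default.
* **Duplicates** — same-day duplicate measurements collapse to the last
  value of the day, with a logged count.
* **Effectiveness** — the flag is strictly `ttr > 0.65`; a TTR of
  exactly 65% is *not* effective, and undefined TTRs (fewer than two
  usable measurements) are excluded from proportions.

## The dose and schedule engines

The titration protocol is six rules applied in priority order (hold
state first, then the hold trigger, then the band rules). Two
resolutions were needed:

* For a range with upper limit ≥ 2.8 the no-change zone
  [lower − 0.2, upper + 0.2] overlaps the hold trigger INR > 3. The hold
  rule is stated unconditionally, so it takes precedence; the
  dose-decrease window (upper + 0.2, 3] is then empty for such ranges,
  which matches its printed inequality.
* Resuming after a multi-day hold subtracts 0.25 tablets from the
  pre-hold dose once, regardless of hold length.

Doses are kept in tablets (quarter-tablet resolution) and never
converted to milligrams — tablet strength is deployment-specific. The
dose floor at zero is our own guard.

The monitoring ladder starts weekly; two consecutive in-range results at
the current interval extend it by one week; the cap is four weeks (the
"one month" maximum is encoded as 28 days, keeping all arithmetic in
whole weeks); any dose change — including holds — resets to weekly.
In-range for scheduling means the therapeutic class (inclusive limits),
not the ±0.2 no-change zone: the protocol's wording is "within the
target range". Consequently a patient can be in the no-change zone
(no dose adjustment) yet still fail to extend their interval.

## The synthetic cohort generator

No patient-level data accompany the management protocols, so the
generator exists to give every downstream stage a realistic, seeded,
fully reproducible input. It emulates a two-arm comparison —
app-supported ("WEB") versus conventional outpatient ("NON_WEB")
management over 180 days with ~260 patients per arm — and its defaults
are a documented calibration, not an empirical claim.

Per patient, daily:

* dose sensitivity *s* (steady-state INR gain per tablet) is lognormal
  across patients (median 0.55, CV 0.30) and drifts within patient as a
  lognormal random walk (daily SD 0.015) with rare abrupt jumps
  (probability 0.006/day, SD 0.35 on the log scale) — diet, illness and
  interacting drugs starting or stopping. The drift is what makes
  monitoring speed matter: a drifted patient stays out of range until a
  visit corrects the dose.
* INR relaxes toward the steady state 1 + *s*·*d* of the dose actually
  taken, at fractional rate 0.25/day (warfarin's multi-day response),
  plus Normal(0, 0.05) biological noise, floored at 0.8.
* adherence: each patient has a long-run intake fraction (Beta across
  patients, arm means 0.985 WEB / 0.88 NON_WEB, concentration 8) and
  misses doses in spells of mean 4 days rather than independently — a
  spell produces a deep INR dip, a compensating dose increase at the
  next visit, and an overshoot above range when intake resumes, which
  is how poor adherence degrades *both* tails of the INR distribution.
* observed INR = true INR × lognormal assay error (CV 2.5%), rounded to
  two decimals; visits follow the schedule engine, stretched by a
  multiplicative lognormal delay (σ 0.01 WEB, 1.3 NON_WEB; floored at 1
  — patients come late, not early), with hold rechecks next-day and
  undelayed, and no realised gap beyond 42 days.
* daily event hazards: minor/severe bleeding scale as
  base·exp(8·max(0, INR − upper)) and thromboembolism as
  base·exp(5·max(0, lower − INR)); the steep supratherapeutic slope
  concentrates bleeding risk in the excursion tails, where the arms
  genuinely differ. A severe bleed or thromboembolic event is fatal with
  probability 0.15; death censors the trajectory.

The two arms differ **only** through visit delay and adherence — the
mechanisms app support plausibly improves — never through different
dosing or scheduling rules. Under the default calibration (and across
seeds) the WEB arm's mean Rosendaal TTR sits near 82% versus ~72%
NON_WEB with SDs near 22/26 percentage points, effectiveness proportions
near 78% versus 64%, ~10 INR checks per patient, and minor-bleeding
incidence near 7–9% WEB versus 9–12% NON_WEB.

What the generator does *not* emulate: genotype effects (CYP2C9/VKORC1),
drug-specific interaction magnitudes, seasonal diet, measurement
devices' differences, staggered enrolment, or clinician deviations from
the stated rules. Passing tests on synthetic cohorts therefore
demonstrate the pipeline's internal correctness and the stated
mechanisms' consequences — not that real cohorts behave this way.

## The comparison layer

* Continuous variables pass a Kolmogorov-Smirnov normality gate per
  group (plain KS against a normal with sample-estimated parameters —
  deliberately not Lilliefors-corrected, and documented as approximate);
  both pass → pooled-variance Student t with mean (SD) summaries, else
  Mann-Whitney with median (IQR).
* 2×2 tables use Fisher's exact test when any expected *or observed*
  cell count is below 5, else χ² with Yates continuity correction
  (the default in the clinical statistical software this mirrors; a
  flag disables it). The observed-count clause matches how sparse rows
  — e.g. a zero cell with expected counts above 5 — are conventionally
  handled in clinical reporting.
* Percentages are always recomputed from counts at one-decimal
  rounding; group denominators always come from the registry at
  analysis time — published denominators are sometimes internally
  inconsistent, so none are hard-coded.
* Time-to-first-event curves are Kaplan-Meier per arm with censoring at
  exit or death from another cause, compared by log-rank; each
  patient's first event of each type counts once.
* No multiplicity adjustment is applied: per-row p-values are reported
  unadjusted, as is conventional for descriptive secondary tables.
* The two-proportion sample size uses the pooled-variance normal
  approximation with attrition inflation
  `ceiling(n / (1 − attrition))`. Note that for proportions 0.731
  versus 0.66 at α = .05 and 80% power this form requires several
  hundred patients per group; published calculations reporting ~206 per
  group for those inputs likely used a different (continuous-outcome)
  formulation whose inputs were not stated. Only the attrition
  arithmetic (206 → 258 per group → 516 total) is asserted against a
  known chain.

## Problem sizes and determinism

The test suite exercises: 1,000 random series against the TTR
discretization oracle (absolute 1e-3); the dose-rule grid at 0.01 INR
resolution across all five built-in ranges and both hold states; and a
2,000-patients-per-arm cohort for the arm-separation and
event-direction checks. Cohorts are reproducible to the byte from
(config, seed): each patient gets an independent substream derived from
the master seed, and every random quantity is pre-drawn in a fixed
layout. Report writing is deterministic; the manifest lists each file's
sha256.
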