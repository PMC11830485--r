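---
title: "Treat-to-target premixed-insulin titration: rules, analytics and the virtual cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Treat-to-target premixed-insulin titration: rules, analytics and the virtual cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotitr)
```

## The problem

People with type 2 diabetes on twice-daily premixed insulin need their doses
adjusted regularly against self-monitored blood glucose (SMBG), but clinic
capacity makes frequent in-person review impractical. An algorithmic
titration engine reviews each week's uploaded readings against a target band
and proposes bounded dose changes, which a physician accepts or declines.
This package implements such an engine, the outcome analytics that accompany
a titration study, and a virtual-patient simulator so the whole closed loop
can be exercised with no patient data.

## The titration rules

Readings come from two prescribed slots, prebreakfast and predinner, with a
target band of 4–8 mmol/L. Once per 7-day window, per slot:

1. **Deduplicate** to one reading per (day, slot), keeping the earliest.
2. **Classify consistency.** With $n$ readings in the slot, the slot is
   *consistently above* the band when at least $\lceil 4/7 \cdot n \rceil$
   readings exceed the upper edge **and** the slot median exceeds it;
   symmetrically below. Fewer than 4 readings is *insufficient* and never
   moves a dose.
3. **Map to the governing dose** (cross-over): prebreakfast readings govern
   the evening premix (it acts overnight on fasting glucose); predinner
   readings govern the morning premix.
4. **Step.** Consistently-high slots earn the governing dose a fractional
   increment: 15% when the slot median is within 2 mmol/L of the band edge,
   20% beyond that (the *severity margin* grades the response while
   respecting the protocol's 15–20% ceiling). Consistently-low slots earn
   the symmetric decrement.
5. **Hypoglycemia precedence.** Any level-2 reading (< 3.0 mmol/L), or ≥ 2
   level-1 readings (3.0–3.9 mmol/L), in a slot forbids an increment that
   week and forces a decrement of the governing dose — severe tier (20%) if
   level 2 occurred, moderate (15%) otherwise. Independently, a level-2
   reading triggers an *urgent* out-of-cycle severe decrement on the day of
   upload, at most once per slot per window.
6. **Quantise and bound.** Deltas round half-away-from-zero to whole pen
   units, with a minimum effected change of 1 U; $|\Delta| \le
   \lceil 0.20\,d\rceil$ always holds for current dose $d$; doses floor at
   0 (a zero dose is reported `capped`, never pushed negative — nor
   incremented, since the ceiling is proportional); and the resulting total
   daily dose (TDD) is truncated to a configurable 1.5 units/kg safety cap,
   truncated slots reported `capped`.
7. **Approval gate.** Every recommendation is `pending` until accepted or
   declined exactly once; only acceptance activates the new regimen.

All constants live in `titrationConfig()`. The operational meaning of
"consistently", the severity tiers, the two-level-1 trigger, the urgent
threshold and the TDD cap are deliberately conservative conventions — they
are the package's own choices where a published protocol leaves the rule
table unspecified, and each is configurable so alternative readings of the
protocol can be expressed.

Two further conventions worth making explicit:

- The 15–20% step is applied **per dose**, not to the TDD; per-dose steps
  are what a premix pen user actually changes.
- With an odd week of 7 readings, a slot median outside the band already
  implies ≥ 4 readings outside, so the `mixed` classification (median out,
  count short) only arises for even reading counts.

## Hypoglycemia analytics

Levels follow the consensus definitions: level 1 = 3.0–3.9 mmol/L
(inclusive), level 2 < 3.0 mmol/L, level 3 = external assistance required —
defined by the assistance flag and dominating any concurrent glucose value.
Episode extraction merges successive qualifying readings closer than a
60-minute debounce gap (with no normal reading in between) into one episode
recorded at the lowest glucose: repeated confirmatory strips are one
clinical event. Whether a study counts strips or debounced events is rarely
stated; the gap is configurable and `debounce_gap_min = 0` reproduces
strip counting exactly. Episodes are assigned to 12-week halves of the
24-week study window.

Adherence is completed/prescribed SMBG (84 days × 2 = 168 per period);
incidence is episodes per participant per period. HbA1c conversions use the
NGSP→IFCC master equation $(\%{-}2.15)\times 10.929$ and the ADAG estimated
average glucose line $\mathrm{eAG} = 1.59\,\mathrm{HbA1c}\% - 2.59$ (mmol/L),
whose inverse round-trips to machine precision. Reported percentages use 1
decimal and incidences 2, matching conventional display precision.

## The virtual cohort

The simulator is deliberately the *simplest* model under which every
closed-loop property has a closed-form oracle; it makes no physiological
claim beyond monotone dose response.

- **Eligibility and moments.** Patients are rejection-sampled to the
  enrollment criteria (HbA1c 7.5–9.9%, TDD < 1 unit/kg, BMI ≤ 40) from
  normal distributions with means/SDs matching the study population:
  HbA1c 8.6 (0.7) %, TDD 0.73 (0.31) units/kg/day, BMI 29.0 (3.6),
  weight centred on 78.5 kg (the weight implied by 57.3 units/day at
  0.73 units/kg/day). Note that the < 1 unit/kg truncation necessarily
  shifts the realised dose mean below 0.73; tests compare against the
  truncated-normal expectation.
- **Dose response.** A reading in slot $s$ on day $t$ is
  $\max(0.5,\; \theta_s - \beta\, d_{g(s)}(t)/w + \varepsilon_t)$, rounded
  to the glucometer's 0.1 mmol/L: setpoint $\theta_s$, sensitivity $\beta
  \sim N(5, 1.5^2)$ (truncated > 0.5) in mmol/L per unit/kg, governing dose
  $d_{g(s)}$, weight $w$, noise $\varepsilon \sim N(0, 1.0^2)$.
- **Setpoints.** Chosen so the baseline mean latent glucose equals the eAG
  of the baseline HbA1c, split ±2.4 mmol/L between slots — the offset the
  baseline fasting glucose (8.7 mmol/L) and eAG of HbA1c 8.6% (11.1 mmol/L)
  imply, with fasting the lower slot.
- **Adherence.** Each prescribed reading is performed with per-patient
  probability drawn from U(0.94, 1.0) (cohort adherence ≈ 97%).
- **HbA1c kinetics.** A state $H_t$ follows an EWMA of daily mean latent
  glucose with time constant 35 days ($\alpha = 1 - e^{-1/35}$), mapped
  through the inverse eAG line; this is the simplest kinetics reproducing a
  larger early than late HbA1c change. Labs add N(0, 0.1²) % (HbA1c) and
  N(0, 0.3²) mmol/L (FPG, drawn from the prebreakfast latent mean) of
  laboratory noise at weeks 0, 12 and 24.
- **Seeding.** The trial seed drives cohort sampling; each patient's
  trajectory runs on a seed derived deterministically from (trial seed,
  patient index), so per-patient streams are order-independent and the whole
  trial is byte-reproducible.

### What the simulator does and does not emulate

It emulates the statistical skeleton the titration loop needs: eligible
baseline moments, twice-daily readings with misses, monotone dose response,
Gaussian-tail hypoglycemia, urgent responses, weekly bounded steps, and lab
draws. It does **not** model meals, exercise, carbohydrate counting,
glucose–insulin dynamics within a day, weight change, or behaviour change.
Two consequences deserve emphasis:

- Under the default linear response, closing an eAG gap of ~3 mmol/L
  requires large dose increases, so titrated trials typically converge near
  the TDD safety cap with week-24 doses well above what the study observed.
  The study itself attributes much of its glycemic improvement to factors
  beyond dose (behaviour change with structured SMBG); an optional
  `setpoint_drift` parameter can express such drift, but the package makes
  no claim to reproduce the trial's −1.2% HbA1c effect size and no test
  asserts it.
- With the default within-day SD of 1.0 mmol/L, readings that have settled
  into the band leave the level-1 tail ≈ 3–4 SDs away, so full-loop runs
  produce few or no hypoglycemia episodes; the hypoglycemia and urgent
  pathways are therefore additionally exercised under a high-variability
  configuration in the tests. Passing tests show the loop's logic is
  correct under the stated model, not that real cohorts would see these
  episode rates.

## Numerical choices and degenerate inputs

- Rounding of dose deltas is half-away-from-zero (`floor(|x| + 0.5)`), the
  convention a pen user applies; R's banker's rounding is never used for
  doses.
- Consistency fractions are compared with a 1e-9 slack so 4/7 of 7 readings
  counts as meeting a 4/7 threshold despite floating-point division.
- Glucose readings are validated to (0, 50) mmol/L; malformed rows are
  rejected with row numbers, and file readers abort when ≥ 5% of rows are
  bad.
- Empty slots are `insufficient`; empty reading streams yield empty episode
  tables; a single-participant summary reports `NA` SDs and flags the
  degenerate cell; an infeasible generator configuration (rejection rate
  > 99%) errors rather than looping.
- Ties when the TDD cap truncates two competing increments are broken
  deterministically (larger delta first, morning first on equal deltas).

## Problem sizes used by the test-suite

Oracle equivalence enumerates all windows of up to 4 readings per slot from
a 5-value grid spanning the clinical range, across several dose levels, plus
2000 random two-slot windows; the safety-precedence search runs 10,000
random windows; Monte-Carlo dose-response checks use 10,000 replicates;
parameter recovery and reproducibility use a 25-patient, 24-week trial and a
10-patient, 12-week trial respectively. These sizes give the properties
comfortable statistical resolution while keeping a full run in minutes.

## Known limitations

- The rule constants are declared approximations of an unpublished rule
  table; they are configurable but the defaults carry no external
  validation.
- Sensitivity recovery by per-patient regression is mildly optimistic
  because titration-induced dose variation is exogenous only across weeks;
  within-week feedback (urgent decrements reacting to the same day's noise)
  introduces a small endogeneity that the 10% recovery margin absorbs.
- BMI is carried as a constant per patient; the modest weight gain that
  accompanies improved glycemia in practice is not modelled.
- FPG is simulated as the prebreakfast latent mean plus laboratory noise;
  venous–capillary differences are ignored.
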