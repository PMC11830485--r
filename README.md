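# glucotitr

Algorithm-guided titration of twice-daily premixed insulin from
self-monitored blood glucose (SMBG), with the safety and outcome analytics of
a treat-to-target titration study and a virtual-patient simulator that runs
the complete closed loop in silico.

It is aimed at researchers and engineers building or evaluating
SMBG-driven insulin dosing systems for type 2 diabetes: the rules engine is a
reference implementation of a weekly treat-to-target adjustment protocol, and
the simulator provides a fully reproducible test bed when no patient data can
be shared.

## The method

Participants on a twice-daily premixed regimen measure capillary glucose at
two prescribed slots (prebreakfast and predinner). Every 7 days the engine
reviews each slot's readings against a target band of **4–8 mmol/L**:

- A slot whose readings *consistently* exceed the band (≥ 4 of up to 7
  readings above the edge **and** slot median above it) earns its governing
  dose an **increment of 15%** — 20% if the slot median is more than
  2 mmol/L beyond the edge. Consistently low readings earn the symmetric
  decrement.
- **Cross-over convention:** the evening premix governs the next morning's
  fasting (prebreakfast) glucose; the morning premix governs predinner
  glucose.
- **Hypoglycemia precedence:** any level-2 reading (< 3.0 mmol/L), or two or
  more level-1 readings (3.0–3.9 mmol/L), in a slot forbids an increment that
  week and forces a decrement of the governing dose. A level-2 reading also
  triggers an **urgent out-of-cycle decrement** the day it is uploaded (at
  most once per slot per window).
- Deltas are rounded half-away-from-zero to whole pen units (minimum effected
  change 1 U), never exceed 20% of the current dose, and the total daily dose
  (TDD) is truncated to a 1.5 units/kg safety cap.
- Every recommendation passes a **physician approval gate** and is applied
  only on acceptance.

The analytics layer classifies hypoglycemia into consensus levels 1/2/3,
debounces confirmatory strips into episodes, and computes SMBG adherence
(completed / prescribed, with 84 days × 2 = 168 prescribed per 12-week
period), per-period incidence per participant, glycemic/dose/BMI summaries,
and the standard HbA1c conversions

    IFCC (mmol/mol) = (NGSP% − 2.15) × 10.929
    eAG  (mmol/L)   = 1.59 × NGSP% − 2.59

The simulator draws an eligible virtual cohort (HbA1c 7.5–9.9%, TDD < 1
unit/kg, BMI ≤ 40; moments matching the study population) with a latent
linear dose–response per patient — reading = slot setpoint − sensitivity ×
governing dose/kg + noise — and HbA1c kinetics as an exponentially weighted
average of mean latent glucose (time constant 35 days) mapped through the
eAG relation. See the methods vignette (`vignettes/insulin-titration.Rmd`)
for every parameter and the design rationale.

## Worked example

One review window in which prebreakfast readings run 9–11 mmol/L while
predinner readings sit in band:

```r
library(glucotitr)
w <- data.frame(slot = rep(c("prebreakfast", "predinner"), each = 7),
                glucose = c(10,10,9,11,10,10,9, 6,6,7,6,5,6,6))
rec <- recommendDoses(w, regimen(30, 20, 75))
rec
#> Weekly dose recommendation (pending)
#>   morning  +0 U (in_range, tier 0%): 30 -> 30 U
#>   evening  +3 U (hyper_increment, tier 15%): 20 -> 23 U
activeRegimen(applyApproval(rec, "accept"))
#> Premixed insulin regimen: 30 U morning + 23 U evening (TDD 53 U, 0.71 U/kg at 75.0 kg)
```

The high fasting readings implicate the *evening* premix (cross-over), the
median of 10 is within 2 mmol/L of the band edge so the moderate 15% tier
applies, and 15% of 20 U rounds to +3 U.

A full 24-week closed-loop trial on 25 virtual patients:

```r
tr <- runTrial(simConfig(n_patients = 25, weeks = 24, seed = 1))
tr$summary
#> In-silico titration trial summary (N = 25 participants, 24 weeks)
#>
#> Glycemic outcomes, insulin doses and BMI by timepoint (mean (SD) [n]):
#>   hba1c_pct         wk0  8.62 (0.48) [25]  wk12 7.56 (0.44) [25]  wk24 7.28 (0.53) [25]
#>   ...
#> SMBG adherence:
#>   weeks_1_12    97.5% (164/168 per participant)
#>   weeks_13_24   97.8% (164/168 per participant)
#>   overall       97.7% (328/336 per participant)
```

HbA1c falls steeply in the first 12 weeks and more slowly thereafter as
doses converge on the band; adherence reflects the configured per-patient
propensity (~97%). `writeReport(tr$summary, "out/")` writes the tables as
deterministic CSVs plus a text report.

A thin command-line front end over the same functions lives at
`inst/cli/glucotitr.R`:

```sh
Rscript inst/cli/glucotitr.R simulate --seed 7 --out-dir out/
Rscript inst/cli/glucotitr.R analyze --smbg out/smbg.csv --labs out/labs.csv \
    --regimen out/regimen.csv --out-dir report/
```

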