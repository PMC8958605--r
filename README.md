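# iodoscreen

Analysis pipeline for YFP-iodide high-throughput drug screens of sodium
iodide symporter (NIS) function, with a clinical recurrence-risk arm.

## The problem

Radioiodide therapy of thyroid cancer depends on NIS-mediated iodide
uptake, which is frequently lost in tumors. One route to drug discovery is
a halide-biosensor screen: cells co-expressing NIS and a halide-sensitive
yellow fluorescent protein (YFP) are treated with a compound library,
sodium iodide is injected, and drugs that *increase* iodide influx reveal
themselves by *quenching* YFP fluorescence. `iodoscreen` implements the
full analysis chain for such screens, plus the downstream clinical
question — whether the targets of hit drugs carry prognostic information
for recurrence in expression + survival cohorts.

The package is aimed at screening groups who have plate-reader exports and
want reproducible, tested hit calling, and at analysts who want the
risk-score machinery exercised against synthetic cohorts with known ground
truth before trusting it on real data.

## The statistics at its core

For each well, the percent quench between the pre-injection reading and
cycle 4 after injection is

    %YFP = (YFP_0 − YFP_4) / YFP_0 × 100

and is normalized twice by interquartile means (spreadsheet TRIMMEAN with
proportion 0.5): per plate (S_IQM = %YFP / μ_IQ, removing plate effects)
and per well position across the screen (S_IQMW = S_IQM / μ_IQW, removing
edge and dispenser effects). The hit statistic is

    ΔYFP = [S_IQMW(drug) − mean S_IQMW(plate-matched DMSO)] / SD_screen-wide(S_IQMW of DMSO)

A drug well is a hit when ΔYFP > 1.5 **and** viability ≥ 70% of vehicle.
Assay quality is gated per plate by the Z′ factor
`1 − 3(SD_p + SD_n)/|mean_p − mean_n|` (suitable above 0.5). The secondary
multi-dose screen is summarized by the positive-peak area under the
response vs log10(dose) curve, its difference against a NIS-free reporter
line (ΔAUC), and a four-parameter-logistic EC50. Radioiodide uptake
converts gamma counts to `pmol 125-I / µg protein = 5000 × (counts /
protein) / 12000`, with a perchlorate-block specificity check.

The clinical arm builds a multi-gene risk score from a multivariate Cox
proportional-hazards fit on log2(FPKM + 1) expression: score_i = Σ_g β_g ·
x_ig, with ROC/Youden cutpoints, Kaplan–Meier stratification, the log-rank
test, and covariate-adjusted multivariate fits.

Every stage has a synthetic-data generator with known ground truth
(`simulate_screen`, `simulate_dose_response`, `simulate_uptake`,
`simulate_cohort`), so the whole pipeline is testable end to end without
any external data.

## Worked example

```r
library(iodoscreen)
report <- run_end_to_end_demo(seed = 1)
print(report)
```

```
Synthetic YFP-iodide screen study (seed 1)
  Primary screen : 1440 wells, 1200 drug wells, 135 hits
  QC             : median plate Z' = 0.834 (floor 0.5)
  Top hits:
    DRUG0864   DeltaYFP  15.54  viability 0.96
    DRUG0450   DeltaYFP  15.35  viability 1.03
    DRUG0802   DeltaYFP  14.71  viability 1.04
    DRUG0663   DeltaYFP  14.36  viability 1.10
    DRUG0132   DeltaYFP  14.13  viability 0.97
  Dose-response (secondary screen):
    DRUG0864   deltaAUC  4.51  EC50 1.73 uM
    DRUG0450   deltaAUC  4.29  EC50 1.99 uM
    DRUG0802   deltaAUC  4.43  EC50 1.77 uM
  Radioiodide    : fold uptake 4.30 +/- 0.08 (NIS-specific)
  Risk model     : 13 genes, score AUC 0.726
  Stratification : high vs low HR 3.45 (95% CI 2.74-4.34), log-rank p 4.64e-29
```

Reading it: 135 of 1200 simulated drugs exceed ΔYFP 1.5 with adequate
viability (the generator plants ~8% true actives, so most hits are real
and the remainder are the expected false-positive tail at 1.5 SD). All 15
plates clear the Z′ > 0.5 window. The three leading hits are taken through
a simulated 10-dose secondary screen: large ΔAUC against the flat NIS-free
control line means the quench is NIS-specific, and the 4PL fits recover an
EC50 near the simulated 1.8 µM. The lead drug's radioiodide uptake comes
back at 4.3-fold over vehicle and collapses under perchlorate. On a
synthetic 600-patient cohort, the 13-gene Cox risk score separates high-
from low-risk patients at a hazard ratio of 3.45.

For file-based use there is a thin CLI (`inst/cli/iodoscreen.R`) with
`simulate`, `validate`, `score` and `demo` subcommands over the same
functions, reading the long-format plate CSV and writing results TSV, QC
TSV and a JSON run manifest.

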