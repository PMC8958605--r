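---
title: "Methods: normalization, hit calling and risk modelling in iodoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, hit calling and risk modelling in iodoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iodoscreen)
```

## The assay and its statistic

A halide-sensitive YFP variant loses fluorescence when intracellular
iodide rises. In a NIS-expressing reporter line, injection of sodium
iodide produces a baseline quench through basal symporter activity; drugs
that enhance NIS function deepen it. The screen's raw readout per well is
the pre-injection fluorescence `YFP_0` and kinetic readings at 3-minute
cycles after injection; scoring uses cycle 4 by default (`cycles_used` in
`screen_config`), so the per-well statistic is the percent quench
`%YFP = (YFP_0 − YFP_4)/YFP_0 × 100`.

Because `%YFP` is a ratio of two readings from the same well, gain
differences between wells cancel before normalization even starts. What
does *not* cancel is anything that affects the quench fraction itself or
that differs between the numerator's biology across plates and positions —
seeding density gradients, temperature and injection-timing differences,
edge evaporation. The chain handles these with two interquartile-mean
(IQM) ratio normalizations:

1. per plate: `S_IQM = %YFP / μ_IQ(plate)`, where `μ_IQ` is the trimmed
   mean over all analyzable wells of the plate;
2. per well position: `S_IQMW = S_IQM / μ_IQW(position)`, where `μ_IQW` is
   the trimmed mean of that position's `S_IQM` values across every plate.

Both trims use spreadsheet TRIMMEAN semantics: with proportion `p`, the
excluded count is `n·p` rounded down to an even number and split equally
between the tails; `p = 0.5` keeps the central half. Because the trim is
aggressive, control wells (strongly quenched NaI positives, unquenched PBS
negatives) fall outside the retained mid-range on a standard layout and do
not bias `μ_IQ`, which is why the plate mean is taken over *all* wells
rather than drug wells only.

The hit statistic standardizes against vehicle:
`ΔYFP = (S_IQMW(drug) − mean S_IQMW(DMSO on the same plate)) /
SD(S_IQMW over all DMSO wells of the screen)`. The plate-matched DMSO term
is the *mean* of that plate's DMSO wells — a deliberate choice over the
median so that each plate's DMSO wells have mean ΔYFP exactly zero by
construction, which gives the calibration tests a sharp anchor. Positive
ΔYFP means more intracellular iodide.

Hits require `ΔYFP > 1.5` (strict inequality; both the bound and the
strictness are configurable) *and* viability ≥ 0.70 of vehicle — a drug
that quenches by killing the cells is not a hit. Ranking is by ΔYFP
descending with lexicographic drug-id tie-breaks so output is
deterministic.

### Degenerate inputs and exclusions

Wells with `YFP_0 ≤ 0` or no finite post-injection reading are flagged,
reported with line numbers, and excluded from every statistic — never
imputed. A plate needs at least 4 analyzable wells for its `μ_IQ`; a zero
`μ_IQ` or `μ_IQW` flags the plate/position and excludes it with a warning.
ΔYFP requires at least 2 analyzable DMSO wells screen-wide and at least
one per plate; both violations are hard errors pointing at the control
layout. A single-plate screen is scoreable but positionally degenerate
(every `S_IQMW` is 1), so multi-plate designs are assumed throughout.

## Assay quality

Per plate, `Z′ = 1 − 3(SD_pos + SD_neg)/|mean_pos − mean_neg|` is computed
from the `%YFP` of the NaI-positive versus PBS-negative control wells;
plates above 0.5 are suitable. `run_primary_screen(qc_required = TRUE)`
turns a failing or incomputable plate Z′ into an error (CLI exit code 3).

## What the screen generator emulates — and what it does not

`simulate_screen` produces, under a single seed, exactly the artefact
structure the normalization chain claims to remove:

* multiplicative log-normal plate effects (SD 0.15, log scale) and
  well-position effects (SD 0.08) on fluorescence, plus 5% multiplicative
  read noise per reading — the ratio form of the Eq-chain removes
  multiplicative distortions exactly, which the invariance tests assert to
  1e-9;
* a baseline quench of 0.30 in every iodide-receiving cell well (DMSO and
  drug wells): the injected iodide enters via basal NIS even without drug,
  which is what makes the plate IQM a meaningful denominator. PBS-negative
  wells receive no iodide (quench 0); NaI positives quench at 0.85;
* a mostly-null drug-effect mixture: 8% of drugs are true actives whose
  *extra* quench above baseline is uniform on [0.30, 0.55] — chosen to
  mirror a primary screen in which roughly 8% of ~1200 library compounds
  scored — applied to the cycle-4 reading with intermediate cycles
  linearly interpolated (scoring uses only cycle 4 by default);
* 8% cytotoxic drugs with viability uniform on [0.10, 0.50], independent
  of activity, so the viability gate has real work to do; the remaining
  drugs sit near full viability (matching the design target of ≥70%
  viability for >90% of drugs).

Defaults are 15 plates × 96 wells: 80 drug wells per plate (columns 2–11,
1200 drugs), column 1 split between NaI-positive (rows A–D) and
PBS-negative (rows E–H) controls, and column 12 carrying the 120 DMSO
wells. The real magnitudes of plate and positional artefacts in any given
facility are unknown; the SDs here are plausible mid-range values fixed
once, not fitted to anything. The generator does **not** emulate
mechanistic quench chemistry, kinetic shape beyond linear interpolation,
spatially *correlated* (non-multiplicative) gradients, compound
fluorescence interference, or carry-over — so a passing test suite shows
the statistics behave as designed under the stated artefact model, not
that any particular real screen is free of other artefact classes.

With these conditions, null drugs' ΔYFP is approximately standard normal
(the calibration tests check mean within ±0.2 and SD within [0.7, 1.4]
across seeds), the expected false-hit rate at threshold 1.5 is the ~7%
upper tail, and actives with ≥0.30 extra quench sit many DMSO SDs high, so
≥95% detection is expected and observed.

## Dose-response summaries

The secondary screen uses 10 doses spanning 0.1–50 µM. "Positive peaks
only" AUC is implemented as the exact integral of the piecewise-linear
response interpolant on the log10-dose axis after clipping at zero —
segments crossing zero are split at the crossing rather than clipped at
their endpoints, so the value matches a dense-grid integration of the
clipped curve to numerical precision and the statistic is monotone in
every response. An optional `largest_peak_only` mode integrates only the
biggest contiguous positive excursion for users who read "peak" narrowly.
ΔAUC subtracts the same statistic computed in a NIS-free reporter line,
cancelling non-specific fluorescence effects.

EC50 comes from a four-parameter logistic fit on log10 dose
(`minpack.lm` Levenberg–Marquardt, ascending and descending starts, best
RSS kept), parameterized in `log10(EC50)` for stability and reported in
the canonical orientation `top ≥ bottom`. A 3PL option fixes the bottom at
zero. The functional form is the standard model behind common EC50
calculators; it is the package's choice, made configurable because
published screens rarely state the exact equation. EC50 is reported only
when the fit converges inside `[min dose/10, max dose×10]`;
flat/unidentifiable series return `fit_ok = FALSE` rather than an error.
Noiseless self-consistency is recovered to ~1e-6 relative error; at 5%
multiplicative noise the median relative EC50 error over 100 replicates is
well under 15%.

Radioiodide uptake uses the gamma-counter conversion
`pmol/µg = 5000 × (counts/protein)/12000` exactly as printed on the
counter protocol; fold change over vehicle propagates SEM by the
first-order delta method for a ratio (the usual choice when arms are
summarized as mean ± SEM), and NIS specificity is flagged when the
+perchlorate / −perchlorate ratio falls below 0.2 (a pipeline default, not
a biological constant).

## The recurrence-risk arm

Expression is transformed `x = log2(FPKM + 1)` before anything else.
Differential expression between groups uses a two-sample nonparametric
test per gene — Kolmogorov–Smirnov by default, Wilcoxon as an option —
with `log2FC` as the difference of transformed-scale group means and
Benjamini–Hochberg adjustment over the full gene family in one step.
Constant genes get p = 1 by convention. Fisher's exact test (two-sided,
conditional odds ratio) handles 2×2 category associations, returning p = 1
on zero margins.

The risk model is a multivariate Cox proportional-hazards fit (Breslow
ties by default, Efron by flag) on the transformed expression of the
signature genes; the risk score is the linear predictor
`Σ β_g x_g`. ROC analysis of score versus event uses the Mann–Whitney
concordance AUC with ties counted ½; the cutpoint is the score median by
default, with Youden's J (`sensitivity + specificity − 1`, ties broken
toward the lower threshold) as the ROC-derived alternative — the criterion
behind "optimal cutoff" choices is rarely stated in clinical reports, so
it is explicit and configurable here. Stratification supports the median
split and a tertile mode (>66th vs <33rd percentile, middle dropped);
groups are compared by Kaplan–Meier curves, the log-rank test, and a
univariate Cox HR, and `multivariate_adjusted` refits jointly with
clinical covariates (one-hot encoded, collinear columns dropped by QR rank
with a warning) so the score's independence can be read off per term.

Using the event *indicator* as the ROC label ignores censoring time — a
deliberate simplification (time-dependent ROC is out of scope) and a known
limitation: with heavy censoring the AUC is an optimistic summary of
discrimination at no particular horizon.

### The cohort generator

`simulate_cohort` draws log-normal FPKM (meanlog 2, sdlog 0.8 — a
realistic right-skewed expression distribution), exponential event times
with hazard `λ_0 exp(Σ β_g x_g)` (linear predictor centered so `λ_0` is
the typical hazard), and independent exponential censoring with its rate
chosen from the mean hazard to land near the target censoring fraction
(0.30). Defaults are 1500 patients, a 13-gene panel with 3 causal genes at
β = (0.60, 0.45, −0.50) — moderate effects chosen so single genes carry
real but clearly sub-maximal discrimination, making "the multi-gene score
beats every single gene" a non-trivial claim to test. Proportional hazards
holds exactly by construction; the generator does not emulate
non-proportional effects, gene–gene correlation, or informative censoring.
Degenerate all-censored draws are retried (bounded at 5, with a warning)
by advancing the seed deterministically.

## Numerical choices, determinism and problem sizes

All generators are pure functions of (spec, seed); every stochastic stage
of the pipeline and the acceptance script threads one root seed.
Fixed-precision TSV output (8 significant digits) makes results diffable;
round-trip tests assert identity at that precision. Oracle tests compare
the pipeline against straight-loop reimplementations (normalization
chain, to 1e-12), dense-grid integration (AUC, to 1e-9), exhaustive
enumeration (Fisher, concordance AUC, Youden scan) and direct numerical
maximization of the Breslow partial likelihood (Cox, to 1e-4).

Test and acceptance problem sizes — 4–15 plates, 100 dose-response
replicates, cohorts of 300–1500 — were chosen as the smallest sizes at
which the Monte-Carlo tolerances above are comfortably stable across
seeds; the whole suite runs in well under a minute on one core.

## Known limitations

* The normalization chain assumes multiplicative artefacts; additive or
  spatially smooth gradients would call for B-score/loess methods, which
  are deliberately out of scope.
* Replicate drug wells are averaged implicitly through position
  normalization only; the pipeline treats each well independently at hit
  calling.
* The EC50 model form and the perchlorate specificity cutoff are
  conventions, not estimates.
* Risk-score ROC uses the event indicator, not censoring-aware AUC.
* Synthetic cohorts cannot stand in for any real tumor cohort; parameter
  recovery there demonstrates correctness of the machinery, not clinical
  validity of any particular gene signature.
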