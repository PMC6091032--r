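---
title: "Methods: VCO2-only REE estimation and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VCO2-only REE estimation and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The estimation problem

Indirect calorimetry (IC) computes resting energy expenditure from measured
oxygen consumption and carbon dioxide production with the nitrogen-free Weir
equation, `REE = (3.941·VO2 + 1.106·VCO2) × 1440` (gas rates in L/min,
REE in kcal/day). Ventilators measure VCO2 continuously but not VO2; fixing
a respiratory quotient `RQ = VCO2/VO2` and substituting `VO2 = VCO2/RQ`
yields the VCO2-only estimator
`REE-VCO2 = (3.941/RQ + 1.106) · VCO2 × 1440`. The package evaluates this
estimator against the IC reference with a standard method-comparison
battery, and calibrates a simple linear alternative by ridge regression.

Two consequences of the algebra shape everything downstream. First, the
multiplier `3.941/RQ + 1.106` is strictly decreasing in RQ, so for a fixed
VCO2 the estimate shrinks as the assumed RQ grows; across an RQ grid the
mean difference from a fixed reference is therefore monotone. Second, for a
fixed RQ the estimator is a positive rescaling of the block VCO2, so Pearson
correlation with the reference is identical across the grid and only
location/scale-sensitive metrics (bias, concordance, agreement bands)
distinguish the RQ choices.

## Units

All public interfaces take gas rates in **mL/min**, the unit in which
ventilators and calorimeters report them; conversion to L/min happens once,
inside the Weir algebra. A single declared convention guards against the
1000-fold errors this domain is notorious for. The Weir coefficients are
configurable (`weir_coefficients()`) for sensitivity analysis; the two-term
nitrogen-free form is used throughout, since urinary-nitrogen data are not
part of this setting. The RQ sanity bounds (0.3, 2.0) are deliberately loose
unit-error guards, not a clinical range (physiological values run from ~0.7,
fat oxidation, to ~1.0, carbohydrate).

## Pairing: 6-hour preceding blocks

Each IC measurement at time `t` is paired with the arithmetic mean of the
ventilator VCO2 records in the half-open window `[t − 360, t)` minutes: the
six hours strictly preceding the assessment. The half-open convention avoids
double-counting a record sitting exactly on a boundary, and "preceding"
(rather than centred or calendar-aligned) reflects how a bedside clinician
would use the trace — only data already recorded at assessment time.
Coverage is the number of records present divided by the number expected at
the trace's nominal step; windows below `min_coverage` (default 0.8, a
choice of this package — no completeness rule is standard) are excluded with
a warning rather than interpolated, because gap interpolation would
manufacture data precisely where the device was least reliable. Duplicate
trace timestamps keep the first occurrence.

## The agreement battery

For each grid RQ (default {0.75, 0.80, 0.85, 0.89}, the values commonly
assumed clinically):

* **Bias**: mean and sample SD (n−1) of estimate − reference.
* **Percentage error / percentage difference**: the validation literature
  prints both without defining them, and the printed values cannot identify
  the formulas. Both are therefore explicit modes:
  `pct_error` defaults to mean(|est − ref|/ref), with Critchley's
  1.96·SD(diff)/mean(ref) criterion as an alternative; `pct_difference`
  defaults to mean(|est − ref|/pair mean), with the signed mean relative
  difference as an alternative. The report states fractions.
* **Correlation**: Pearson r with the Fisher-z 95% CI (via `cor.test`).
* **Concordance**: Lin's concordance correlation coefficient with
  n-denominator moments. CIs by nonparametric bootstrap percentile
  (default 2000 resamples, seeded) — robust to the visibly non-normal
  differences — with Lin's 1989 asymptotic z interval as the cheaper
  alternative. |CCC| ≤ |r| always; this inequality is fuzz-tested.
* **Agreement bands**: fraction of pairs with est/ref inside the closed
  intervals [0.85, 1.15] and [0.95, 1.05]. Closed, because "within 85% and
  115%" most naturally includes the endpoints; at continuous data the choice
  is measure-zero anyway.
* **Bland–Altman**: differences against pair means, limits of agreement
  bias ± 1.96·SD. The 1.96 normal quantile is not t-adjusted: at hundreds of
  pairs the difference is far below reporting precision.

All pairs are pooled across patients, as is conventional in this literature;
repeated-measures-adjusted limits of agreement are deliberately out of
scope, and the pooled CIs ignore within-patient clustering — a known
limitation that the cohort's ~60% between-patient variance share makes
material for inference, though not for the point estimates.

## Ridge calibration and the simplified formula

`fit_ridge` regresses reference REE on VCO2 with a squared-coefficient
penalty on the standardized predictor (mean 0, SD 1; the intercept is
unpenalized). With one predictor the solution is closed-form per penalty
value; the penalty is selected from a log-spaced grid (1e-4 … 1e2, 25
points) by 10-fold cross-validated squared error, with folds shuffled by a
seed and standardization recomputed inside each training fold. With a single
well-conditioned predictor the penalty choice barely matters — the selected
penalty is typically near the bottom of the grid and the fit is essentially
OLS (an equality tested at penalty 0) — but the penalized form keeps the
procedure well-defined under near-constant predictors and matches how such
calibrations are reported. R² is in-sample on the selected fit.

The fitted coefficients are rounded half-away-from-zero to integers
(`round_to_simplified`) to produce a memorable bedside formula
`REE = a + b·VCO2`, which is then re-evaluated with the full battery on the
ventilator pairs. Calibration defaults to the calorimeter's own VCO2 — its
agreement there is the ceiling of VCO2-only estimation, uncontaminated by
between-device error — while evaluation always uses the ventilator blocks;
a `calibration_source` switch exposes the other choice, since published
descriptions are ambiguous about which set such formulas were derived on.

## The synthetic cohort

No patient-level data accompany the validation studies this pipeline is
designed around, so the generator emulates their reported marginal
statistics: 80 patients; measurements per patient drawn from a fixed
discrete distribution on 1..15 coarse-fit so the quartiles are 2/3/7 (the
exact distribution is unidentifiable from a median and IQR); true REE
2059.5 ± 491.7 kcal/day split 60/40 between a patient-level random effect
and within-patient variation (no published guidance; 60/40 encodes that
patients differ more than occasions), truncated above 500 kcal/day; true RQ
from a truncated normal on [0.60, 1.10] whose latent location and scale are
solved by moment matching so the **marginal** mean and SD equal the
configured 0.75 and 0.07 — naive truncation on this asymmetric interval
would bias the mean upward by ~0.003 and shrink the SD by ~4.5%.

True VCO2 is then solved from the Weir relation (`VO2 = VCO2/RQ`), so the
IC-observed gases reproduce the true REE exactly: IC is the reference
method and carries no error in this model. The ventilator trace is a step
function of the per-measurement true VCO2 multiplied by a device bias
(default 1) and stationary lognormal AR(1) noise (unit mean; AR coefficient
0.8 at 5-minute steps, encoding the slow drift of real ventilator VCO2).
The noise SD defaults to 1.289, the value `tune_vent_noise` returns for a
pooled estimator–reference correlation of 0.51 — the level reported for
6-h ventilator blocks against calorimetry in adults. A correlation that low
requires per-record noise larger than the signal; after 72-record block
averaging (with the AR(1) correlation limiting the averaging gain) it
corresponds to ~38% relative SD on the block mean, which should be read as
all between-device discrepancy — measurement error, true temporal
variation between the 20-minute IC window and the 6-h block, RQ drift —
collapsed into one dial, not as a claim about raw sensor precision.

Randomness is disciplined: one root seed yields per-patient child streams,
so extending a cohort never perturbs existing patients, and identically
configured runs are byte-identical through the whole pipeline.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: ventilation-mechanics artefacts (air leaks,
changing minute ventilation, FiO2/PEEP instability), missingness that
correlates with clinical state, RQ drift with nutrition, device
recalibration effects, and any dependence of the ventilator error on the
signal level beyond proportionality. Conclusions about the *statistical
machinery* transfer; conclusions about *clinical accuracy* do not.

**A structural caveat.** The published marginal moments this generator
targets are mutually inconsistent under the Weir relation: with REE
2059.5 kcal/day and RQ 0.75, the implied mean VCO2 is ≈ 225 mL/min, not the
reported 244.5, and no admissible REE–RQ correlation closes the gap (the
same tension is visible in the source values themselves, where the fixed-RQ
multiplier times the reported mean VCO2 does not reproduce the reported
mean estimate). The generator follows the Weir-consistent chain with the
REE and RQ moments as configured and an unbiased ventilator
(`vent_bias = 1`); its block-VCO2 mean consequently sits ≈ 8% below the
published figure, and the moment-recovery test records that discrepancy
rather than hiding it behind a bias factor.

## Numerical choices and degenerate inputs

Truncated normals are sampled by rejection (exact; the truncation points sit
far enough from the mode that rejection rates are negligible). The
moment-matching solve uses closed-form truncated-normal moments under
Nelder-Mead to 1e-14 relative tolerance. Zero-variance inputs error in the
standalone correlation functions (they have no defined answer) but
degrade to `NA` with a warning inside the battery, so an all-constant
estimator — e.g. a constant trace, or the zero formula — can still be
summarised by its bias and agreement. Penalty ties in cross-validation go to
the smallest penalty; duplicate trace timestamps keep the first record;
quantiles use linear interpolation (type 7).

## Problem sizes

The test suite exercises cohorts of 5–1200 patients. Moment recovery is
checked at ~5500 measurements with leave-one-patient-out jackknife standard
errors for the clustered REE and block-VCO2 statistics (naive 1/sqrt(N)
errors would be about half their true size at the 60/40 variance split);
noise tuning bisects on ~1300-measurement cohorts and verifies at ~5000;
brute-force reproducibility of the performance table is checked at ~500
pairs, ridge recovery at n = 5000, and limits-of-agreement coverage at
n = 10000. These sizes give the asymptotic checks comfortable resolution
while keeping the whole suite quick to run.
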