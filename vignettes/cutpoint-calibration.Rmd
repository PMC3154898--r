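---
title: "Calibrating accelerometer intensity cut points in young children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating accelerometer intensity cut points in young children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcal)
```

## The calibration problem

Accelerometers summarise movement as dimensionless counts per epoch.
To turn a week of free-living counts into minutes of sedentary time or
moderate-to-vigorous activity, count thresholds must be calibrated
against a physiological criterion in the target age group. `accelcal`
implements one complete calibration design for 7–8-year-olds: a
laboratory protocol of seven self-paced activities spanning the
intensity range, with counts recorded in 15-second epochs and oxygen
uptake measured by portable indirect calorimetry, reduced to one count
and one energy-expenditure value per child per activity, and turned into
four intensity categories by a mixture of empirical thresholding and
discriminant analysis.

The original measurements are not distributable, so the package ships a
seeded generator that emulates their statistical structure. Every stage
downstream of the generator treats its output exactly as it would treat
user-supplied CSV files.

## Data reduction

Each activity bout contributes a 2-minute steady-state window: minutes
2.5–4.5, chosen to avoid both the onset transient of oxygen uptake and
end-of-task anticipation, except lying, where minutes 22.5–24.5 of the
30-minute bout are used. Windows are half-open `[start, end)` and epochs
belong to a window by their start time; the protocol clock restarts at
zero for every bout (inter-activity gaps are not modelled).

Within the window, epoch counts are summed per minute (four 15-s epochs)
and the two minute-sums averaged into one counts-per-minute (cpm) value.
For complete windows this "sum then mean" equals the direct 8-epoch mean
scaled to a minute; the per-minute form is kept for fidelity to the
design and because it generalises to other epoch lengths that divide 60.

Oxygen uptake is averaged over the window (the arithmetic mean; the
procedure defines steady state but not a summary statistic, and the mean
is the natural choice for a plateau) and converted to energy expenditure
at 1 L O₂ = 4.825 kcal:
`EE [kcal·kg⁻¹·hr⁻¹] = VO₂ [ml·kg⁻¹·min⁻¹] · 60 · 4.825 / 1000`.

METs are child-specific: activity EE divided by the child's *predicted*
basal metabolic rate. The adult convention (1 MET = 3.5 ml·kg⁻¹·min⁻¹)
is inappropriate at this age, where resting uptake is substantially
higher. BMR is predicted by the sex-specific Schofield
weight-and-height equations for ages 3–10 (MJ·day⁻¹, W in kg, H in m):

* male: `0.082 W + 0.545 H + 1.736`
* female: `0.071 W + 0.677 H + 1.553`

converted at 239.006 kcal·MJ⁻¹ (the thermochemical factor) and expressed
per kg per hour. The coefficient table is data
(`schofield_coefficients()`), so the weight-only variant can be swapped
in; ages outside 3–10 are an error rather than a silent extrapolation.
On default synthetic cohorts the mean predicted BMR is close to 1.58
kcal·kg⁻¹·hr⁻¹ (≈ 5.46 ml O₂·kg⁻¹·min⁻¹), at the low end of the
sedentary EE range, which is what makes sitting METs average ≈ 1.4.

## What the generator emulates — and what it does not

`generate_study()` produces, per child and activity, an epoch-level
count series and an oxygen-uptake series, plus cohort anthropometrics.

**Anthropometrics.** Height and weight are a bivariate normal truncated
to positive values (means 132.9 cm / 31.3 kg, SDs 6.5 / 6.8) with
correlation 0.7 — a typical paediatric height–weight correlation, chosen
once since the design gives no value. 29 of 53 children are male; 39/14
are assessed morning/afternoon, with no session effect on EE (none was
observed in the calibration sample).

**Locomotor counts.** For each non-sedentary activity the generator
draws a child-level cpm effect and adds epoch noise. The variance split
follows the one-way random-effects decomposition: with ICC target ρ and
k = 8 window epochs, between-child variance is `ρT` and within-child
`(1−ρ)T` with `T = k·SD² / ((k−1)ρ + 1)`, so that simultaneously (a) the
per-child 2-minute mean is `Normal(mean_cpm, sd_cpm)` across children
and (b) the within-child epoch ICC hits its target. ICC targets default
to 0.77–0.90 per activity, the observed stability range. Epoch values
are clipped at zero and rounded half-up to integer counts.

**Sedentary counts.** Zero-inflated: with probability 0.66 (sitting) or
0.62 (lying) the whole series is zero. Otherwise a child-level count
rate comes from a two-part log-normal mixture — a body of small values
and a rare large-outlier component — with weights and log-moments
calibrated to the published per-child sitting vector
(`reference_sitting_counts()`: 35 zeros; 14 values between 1.5 and 96.5;
3 outliers at 251–483), and epoch counts are Poisson at that rate. The
printed vector totals 52 values rather than the stated 53 participants;
the generator targets the stated 66% zero fraction and treats the count
as an erratum in the source table.

**Oxygen uptake.** A mono-exponential rise to plateau,
`vo2(t) = plateau · (1 − e^(−t/τ))` with τ = 30 s by default, so the
2-minute window (starting at minute 2.5) sits ≥ 5 time constants into
the bout and the residual rise biases window means by well under 1%.
The plateau EE is `Normal(mean_ee, sd_ee)` across children, drawn
jointly with the same child's count effect at correlation
`ee_count_corr` (default 0.6 for the walks, 0.2 for jogging — where the
count–EE association was weak — 0.5 for the games, 0 for sedentary).

**Not emulated:** breath-by-breath gas fractions and measurement noise
around the uptake profile, device drift, non-wear time, heart rate, and
the empirical (non-Gaussian) shape of the locomotor count
distributions. That last point matters for interpretation: passing
tests show the pipeline recovers its own generating parameters and the
published *distribution-level* results (boundaries, sedentary/vigorous
AUC), not that Gaussian classes reproduce every published
sensitivity/specificity — the published achieved sensitivities for
light/moderate depend on empirical distribution shape and are surfaced
by the package but never asserted.

## Robust statistics

* **ICC.** One-way random-effects ICC(1,1) — epochs within a bout are
  exchangeable repeats, so no rater structure — with Searle's F-based
  confidence interval. Constant matrices are an error (the estimate is
  undefined), not an NA.
* **Normality gating.** Shapiro–Wilk at α = 0.05 decides between
  Pearson and Spearman for count–MET association, mirroring the
  judgement-based practice the design describes.
* **Grubbs.** The two-sided maximum-studentised-deviation test applied
  one value at a time: flag, remove, re-test. Per-step p-values are
  reported without family-wise correction (that is what "one at a time"
  means operationally); α defaults to 0.05. The critical value is
  `((n−1)/√n)·√(t²/(n−2+t²))` with `t = t_{α/(2n), n−2}`.
* **Medcouple and adjusted boxplot.** The medcouple is the median of
  the kernel `h(xᵢ,xⱼ) = ((xⱼ−m)−(m−xᵢ))/(xⱼ−xᵢ)` over pairs straddling
  the median, with the signum kernel `sign(i+j−1−q)` for pairs tied at
  the median — not optional here, since two-thirds of sitting values
  *are* the median. The O(n²) enumeration is used; cohort-sized inputs
  (tens to hundreds) make the O(n log n) algorithm unnecessary.
  Fences are `[Q1 − 1.5e^(−4MC)·IQR, Q3 + 1.5e^(3MC)·IQR]` for MC ≥ 0
  (exponents −3, 4 for MC < 0), with type-7 (linear interpolation)
  quartiles fixed for reproducibility: on the published sitting vector
  MC = 1 exactly, the upper fence is ≈ 105 cpm, and exactly the three
  printed outliers are flagged. Zero IQR with non-constant data
  collapses the fences to the quartiles (documented, not an error).
* **Group comparisons.** Sex differences use two-sample Welch t tests —
  the design's "paired t-tests with Welch's correction" is internally
  inconsistent (Welch's correction addresses unequal variances of
  independent groups), and sex comparison is inherently two-sample.
  Session differences use Wilcoxon–Mann–Whitney, exact for small
  tie-free samples.

## Cut-point derivation

Sitting is heavily zero-inflated, so no Gaussian boundary is credible
at the bottom of the scale. The sedentary threshold is empirical:
remove adjusted-boxplot outliers, take the maximum remaining value, and
round up to the next multiple of `round_to` (default 100 cpm, the
round-number rule that turns a 96.5-cpm maximum into a 100-cpm
threshold; `round_to = 1` exposes the raw bound, 97).

The upper boundaries come from a univariate homoscedastic LDA over the
three locomotor classes (slow walk, brisk walk, jog): class means,
pooled SD, priors from class frequencies (equal under the balanced
design; configurable). Boundaries are the count values where adjacent
posterior curves intersect:

`x* = (μᵢ + μⱼ)/2 + σ²·ln(πᵢ/πⱼ)/(μⱼ − μᵢ)`

The closed form is cross-checked internally against a bisection solve
of the posterior curves at 10⁻⁶ cpm tolerance, and an intersection
outside the open interval between the class means aborts (a prior so
extreme it swallows a class indicates a misordered model, not a usable
boundary). At the published class parameters the midpoints are 2235.5
and 3857; the published operational values 2240/3840 evidently come
from unrounded study data, and simulated classes at the printed
means/SDs land within 1% of them. A sitting-inclusive four-class fit is
available (`include_sitting = TRUE`) since the design's wording is
ambiguous about it; three classes are the default as only three
posterior curves appear in the design's boundary figure, and the
sedentary boundary is taken from the empirical rule either way.

Raw intersections are always reported; operational cut points are
rounded to the nearest 10 cpm by default (the published values are
round multiples of 10; no rounding rule is stated, so the grain is
configurable and `NULL` disables it). Classification intervals follow
the published table: sedentary ≤ 100 < light ≤ 2240 < moderate ≤ 3840 <
vigorous.

## Evaluation

Each intensity is evaluated one-vs-rest with cpm as the score, the
corresponding calibration activity as positives and the other three
pooled as negatives. The negative set is not specified in the design;
one-vs-rest is the construction consistent with four separate ROC
curves. Sedentary and light use the "low counts positive" direction
with the upper interval bound as the operating cut; moderate and
vigorous use "high counts positive" with the lower bound. (A single
threshold cannot isolate a middle class from both sides — this is why
the light and moderate AUCs hover near 0.6 by construction, for any
reasonable direction choice.)

AUC is computed from ranks (Mann–Whitney form, ties ½) and equals the
trapezoidal area under the empirical curve to machine precision — the
suite checks both routes against each other and against an independent
ROC implementation. Significance of AUC > ½ uses the Mann–Whitney null
distribution: exact when tie-free and `n₊·n₋ ≤ 10⁴`, else the normal
approximation with tie and continuity correction. The optimal point
minimises Euclidean distance to (0, 1) with ties broken toward higher
sensitivity. The misclassification rate is the off-diagonal fraction of
the 4×4 confusion matrix over all n × 4 calibration observations (the
design's description of the numerator as "correctly predicted" is read
as an erratum).

## Numerical and interface choices

* Counts are clipped at zero before rounding half-up (`floor(x+0.5)`) —
  half-to-even would bias counts generated at 0.5-count resolution.
* Posterior curves are evaluated in log space with a log-sum-exp
  normalisation so grid tails do not underflow.
* All randomness flows through a single seed; a fixed seed makes the
  whole study, including written CSVs, byte-identical (floats are
  written at a configured number of decimals, default 3).
* Every JSON artifact embeds the configuration hash for provenance.
* CSV is the sole interchange format; native accelerometer files are
  out of scope.

## Problem sizes in the shipped checks

The test suite and acceptance script use sizes chosen to keep Monte
Carlo error comfortably inside the tolerances they assert: 5 000
replicate children for generator moment recovery (2% bands), 300
children for ICC recovery (±0.05), 10 000–20 000 observations per class
for boundary recovery (1% bands), 200 replicate cohorts for the BMR
mean, 100 seeds for the sedentary AUC, and 2 000 replicates for the
null-uniformity check of the AUC test. The full 53-child pipeline runs
end-to-end in about a second.

## Known limitations

* Gaussian locomotor classes are an approximation; real brisk-walk
  counts were right-skewed with outliers. The pipeline's Grubbs stage
  mirrors how those were handled, but published light/moderate
  sensitivities are not reproducible from the Gaussian surrogate.
* The discriminant is univariate by design; multivariate or
  MET-regression cut-point methods are out of scope.
* Cut points are age-specific. Nothing in the machinery generalises
  them beyond the calibrated age band.
* The ICC confidence intervals assume balanced, complete matrices; the
  pipeline errors on missing cells rather than imputing.
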