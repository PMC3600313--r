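---
title: "Dental age estimation: models, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dental age estimation: models, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentage)
```

## The problem

Dental age (DA) estimates a child's maturity from the radiographic
calcification stages of the seven left mandibular permanent teeth.
Each tooth is rated on the ordinal scale `0 < A < B < … < H`; a
sex-specific weight table converts the seven ratings into a maturity
score S on a 0–100 scale (100 = all seven roots complete), and a
population standard converts S to DA. Because tooth development is
population-dependent, a standard calibrated on one population
systematically over- or under-estimates ages on another; quantifying
that bias (DA − CA) and recalibrating is the core task this package
supports.

## Model and assumptions

**Scoring.** S = Σ over teeth of weight(tooth, stage). A valid weight
table has weight(·, `0`) = 0, weights non-decreasing in stage order,
and stage-H weights summing to 100 (checked to 1e−9 on load). The sum
is order-invariant and bounded in [0, 100] by construction; advancing
any one tooth a single stage can never lower S.

**Chronological age.** CA = (exam date − birth date in days)/365.25.
The half-open 1-year bins [k, k+1), k = 4…13, labelled
`"k.00-k.99"`, partition the validated window [4, 14); subjects
outside it are rejected at ingest unless explicitly admitted for
estimation-only use.

**Conversion.** Table standards return the tabulated age exactly at
grid scores and interpolate linearly in between — the shipped grids
are dense (steps mostly ≤ 1.5 score units), so the interpolation
choice is immaterial at the precision of the tables. Polynomial
standards evaluate `age(S) = b0 + b1 S + b2 S² + b3 S³` directly and
must be strictly increasing on their validity range, which is checked
numerically on a 0.01-score grid at construction. Inversion
(`age_to_score()`) uses bisection on the monotone range to an age
tolerance of 1e−10; target ages up to 1e−4 yr beyond the attainable
endpoints are clamped to the endpoint, which absorbs the 5-decimal
rounding of published tables (e.g. a printed 12.69963 against a model
maximum of 12.6996250…).

**Calibration.** `fit_polynomial()` fits age on score by ordinary
least squares — age is the response because it is the unknown in a
forensic case. The design is centred and scaled internally (the fit
runs on z = (S − mean)/sd, then maps back to raw coefficients exactly)
because the raw basis {1, S, S², S³} with S near 100 is poorly
conditioned for naive normal equations. Degree is restricted to 1 or 3,
the two forms used for this calibration problem in practice.

**Why refit coefficients are canonical.** The published cubic
equations for the Saudi standards carry only 2 significant figures in
the quadratic term; evaluating the printed male equation at S = 25.8
gives ≈ 4.39 where the published table prints 4.28746. The prediction
tables, by contrast, are exact model evaluations rounded to 5 decimals
(the least-squares refit of the table pairs has RMSE ≈ 3e−6 yr). The
shipped canonical models are therefore the refits; the printed
coefficients travel in `metadata$published_coefficients` and match the
refits at their own printed precision (intercepts to 3 dp, cubic terms
to 4 sf). One data quirk: the girls' published table prints the pair
(63.6, 6.28319) twice; the shipped table stores unique pairs, which
leaves the refit unchanged at printed precision.

## Comparison statistics

For each standard, sex and age group the package reports the mean,
SD (n−1), 95% CI (mean ± t(0.975, n−1)·sd/√n) and the two-sided paired
*t* p-value of the DA − CA differences; groups with a single subject
report the mean only rather than being dropped. Whole-sample totals
are size-weighted means of the group means, which equal the pooled
per-subject mean exactly when computed from unrounded values. (Worth
knowing: weighting the *rounded* published boys per-group rows gives
0.7664 → 0.77, the value quoted in the source's running text, while
its summary table prints 0.76 — an internal rounding discrepancy of
the source, not of this implementation; the comparison-table columns
reproduce all printed totals exactly at 2 dp.)

Across standards, a classical one-way fixed-effects ANOVA is followed
by Scheffé post hoc contrasts: for groups i, j the standard error is
√(MSW(1/nᵢ + 1/nⱼ)), the adjusted p is
P(F(k−1, N−k) ≥ (diff/SE)²/(k−1)), and the simultaneous CI half-width
is √((k−1)·F crit)·SE. Scheffé is deliberately conservative (adjusted
p ≥ the unadjusted pairwise-t p, a property the test suite checks on
every simulated instance). Homogeneous subsets follow the convention
of mainstream statistical software for unequal group sizes: the
subset-building SE uses the harmonic mean of all group sizes, means
are sorted ascending, and maximal runs whose extreme-pair comparison
is non-significant form the subsets; each subset reports that
extreme-pair p as its significance (1 for singletons). The
significance level defaults to 0.05 and no correction beyond Scheffé
is applied. Rater reliability uses Cronbach's α with the two rating
sessions as k = 2 items and each (radiograph, tooth) rating as a case,
stages coded ordinally 0…8 with equal spacing — the conventional
choice; pooling across teeth (rather than per-tooth α) is likewise a
choice this package makes explicit.

## The synthetic cohort generator

`simulate_cohort()` emulates the cohort design the pipeline assumes:
per-(sex, bin) counts default to the reference design (217 boys, 205
girls over bins 4–14), CA is drawn uniformly within each bin (no
within-bin distribution is documented for the reference cohorts, and
their per-bin means sit near bin centres), a latent score is obtained
by inverting the generating model at CA, Gaussian rating noise of SD
σ (default 2 score units ≈ one stage step of a dense table) is added
on the *score* scale — rating error is the physical noise source —
and the noisy score is quantised into stages by greedy round-robin
advancement. The greedy decomposition under-shoots its target by less
than one maximal single-stage increment (3.6 score units for the demo
tables; 100/56 ≈ 1.79 is the theoretical minimum for any 7-tooth
8-stage table) and emulates the roughly parallel advancement of teeth
in real children; exact subset-sum matching would add nothing the
quantisation bound does not already control.

Ages outside the generating model's attainable span are clamped before
inversion, so children older than the age at score 100 saturate at
full maturity — the realistic behaviour, and necessary because the
default design itself exceeds the female model's maximum age (12.6996
yr) in the 13–14 bin. `cohort_config(on_uncovered = "error")` restores
strict rejection of uncoverable bins.

**What a green simulation test does and does not establish.** The
generator shares the package's own conversion machinery, so
inverse-pair tests (simulate → score → estimate → DA − CA ≈ 0 at
σ = 0) validate internal consistency, not biological realism. The
generator does not model per-tooth asynchrony, missing teeth,
longitudinal correlation, or non-Gaussian rating error; real-data
biases (examiner drift, cohort selection) are outside its world.

**Parameter recovery and its bias floor.** Refitting the cubic from
simulated cohorts recovers the generating curve, but stage
quantisation leaves a small systematic coefficient bias (measured
≈ 1.3e−6 in the cubic term under the demo tables) at which the error
saturates once n reaches a few hundred subjects. Error shrinkage with
n (≈ √2 per quadrupling) is therefore demonstrable approaching the
reference design size from below, but not beyond it — the floor is
irreducible within an 8-stage system and is a property users
calibrating from staged (rather than continuous) scores should
expect in real data too.

## Numerical and design choices

* Year length 365.25 days (decimal-age convention); real calendar
  dates via `base::Date`, so leap days count.
* Age-group labels use an ASCII hyphen (`4.00-4.99`) for CSV and
  terminal safety.
* Extrapolation outside a standard's coverage is off by default;
  when enabled, table standards extend their end segments linearly and
  results carry an `"extrapolated"` attribute. Estimates at the
  coverage edge deserve suspicion: the method is considered unreliable
  past age ≈ 13.
* Standards whose age coverage excludes a subject yield `NA` (absent),
  not zero — mirroring partially calibrated standards that publish no
  values below age 7.5; group sizes per standard therefore differ.
* The shipped external-population standards are synthetic
  placeholders (bias-shifted copies of the refit Saudi curves, labelled
  `SYNTHETIC` in their provenance); the true Demirjian stage weights
  are likewise not distributable here, so a structurally valid
  synthetic demo weight table ships instead. Conclusions about real
  populations require loading the genuine reference data through the
  documented JSON schemas.
* Reported precision: ages 5 decimals, summary statistics full
  precision in machine output (round on display).

## Known limitations

Stage ratings are consumed, never produced: radiograph interpretation
and the visual stage criteria are out of scope. Only two-session
Cronbach's α is offered for reliability (no κ, no inter-observer
designs). Point predictions only: no centile curves or individual
prediction intervals. The linear-model variant is retained for
comparability but the cubic is the better fit across the score range;
both are only as good as the population they were calibrated on.
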