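---
title: "Methods: twin fetal-sex classification from shallow-WGS NIPT"
author: "twinnipt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin fetal-sex classification from shallow-WGS NIPT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinnipt)
```

## The problem and the model

Cell-free DNA in maternal plasma is a mixture of maternal and placental
fragments. In a singleton pregnancy, fetal sex can be read off the presence
of chromosome-Y fragments. In a twin pregnancy the question is harder: the
classes are female–female (FF), female–male (FM) and male–male (MM), the two
placentas can shed unequally (up to roughly 2-fold), and a mixed pair with a
weakly shedding male placenta produces a chrY signal that overlaps the MM
range at low fetal fraction.

`twinnipt` models each pregnancy with three covariates:

* `normY` — GC-corrected chrY read count divided by total reads. Even in
  all-female pregnancies this is not zero: X–Y homologous regions cause a
  constant mismapping floor (about `4.9e-5` of reads). Each male fetus adds
  signal proportional to its own fetal-fraction contribution.
* `normX` — the analogous chrX frequency, which *decreases* with male
  content (a male fetus carries one X, not two).
* `ff` — the total fetal fraction, externally estimated for real cohorts
  (autosome-based estimators such as SeqFF; their pretrained coefficients
  are deliberately outside this package) or taken from simulator truth plus
  Gaussian estimator noise.

Two classification strategies are fitted by ridge-penalized logistic
regression (see *Numerical choices*):

* **one-step**: a single 3-class multinomial with FF as reference.
* **two-step**: a binomial FF-vs-non-FF decision first — biologically, "is
  any Y chromosome present?", the most reliable split — followed by a
  binomial FM-vs-MM model applied only to non-FF calls. The second-step
  model is trained on the *truly* non-FF training rows, so its fit does not
  depend on step-one errors. Reported probabilities compose by the chain
  rule `{P(FF), (1-P(FF)) P(FM|non-FF), (1-P(FF)) P(MM|non-FF)}`.

Chorionicity enters as prior knowledge, not as a covariate: monochorionic
twins are monozygotic and hence same-sex, so in chorionicity-aware mode that
stratum uses a dedicated FF-vs-MM binomial (`mc_binary`) that cannot emit
FM, while dichorionic samples use the full strategy. In pooled mode all
samples are analyzed together, which is the realistic setting when
chorionicity is unknown; its accuracy is expectedly somewhat lower.

Whether step one "should" be a dedicated binary fit or the 3-class
multinomial collapsed to FF/non-FF is a genuinely open design point; both
are implemented (`two_step`, `one_step`) and the binary two-step is the
default, matching the rationale that the FF split is the high-signal
decision.

## Evaluation

Performance is estimated by leave-one-out cross-validation: every sample is
predicted by a model trained on all other samples (within its stratum in
chorionicity-aware mode). From the resulting confusion matrix,
per-class sensitivity is `correct-in-class / class-total` and specificity is
`correctly-not-called / total-of-other-classes`, the negatives being **all
other samples of the evaluated stratum** (not only those reaching step two —
this convention reproduces the reference arithmetic). Binomial proportions
get 95% **Wilson score intervals**: the Wilson interval is the inversion of
the score test, is well behaved at proportions of 0 and 1, and — unlike
Clopper–Pearson, which gives 0.88 for 45/46 — reproduces every printed
reference bound after 2-decimal rounding:

| x/n   | Wilson lower | Wilson upper |
|-------|--------------|--------------|
| 50/50 | 0.93         | 1.00         |
| 36/36 | 0.90         | 1.00         |
| 45/46 | 0.89         | 1.00         |
| 34/37 | 0.79         | 0.97         |
| 63/66 | 0.87         | 0.98         |
| 74/75 | 0.93         | 1.00         |

Percentages are rounded half away from zero to the nearest integer; CI
bounds to 2 decimals. One known reporting anomaly: a pooled-analysis MM
specificity of 122/125 rounds to 98% under every denominator convention we
tried, while 97% has been reported for that cell elsewhere; the package
reports its own arithmetic.

The twin-vs-singleton fetal-fraction comparison uses the two-sided
Wilcoxon/Mann–Whitney rank-sum test (`stats::wilcox.test`; exact for small
untied samples, normal approximation with tie correction otherwise).

## Fetal-fraction thresholds

Plotting `normY` against fetal fraction, each class follows a straight
line: FF is flat at the mismapping baseline; MM rises with slope
`slope_normY / 2` (both fetuses male, summed contribution `ff/2`); FM rises
half as fast on average, with extra spread from the shedding split. The
package fits per-class ordinary least squares lines
(`fitClassLine`) and reports, per adjacent class pair:

* the **mean-line crossing** — the theoretical minimum fetal fraction above
  which the class means separate, i.e. >50% of cases classify correctly;
* the **band separation point** — the smallest fetal fraction at which the
  mean ± 3 s.d. bands stop overlapping, above which essentially all cases
  classify correctly.

"±3 s.d." is interpreted as the class line ± 3 × its root-mean-square
residual of `normY` (the figure-legend wording is terse enough to allow a
fetal-fraction-spread reading instead; that variant is available with
`band = "ff"`, which propagates `3 * sd(ff)` through each line's slope).
Thresholds are reported in percent with two decimals. Exact threshold values
from the real cohort (2.08% for FM/MM, 0.76% for MM/FF) depend on that
cohort's fitted lines and its SeqFF estimates and are not reproducible from
synthetic data; the package instead verifies the machinery — closed-form
intersection recovery, slope recovery within sampling error, monotone band
widening — and reports the thresholds of whatever cohort it is given.

## The synthetic cohort generator

The generator (`generatorConfig()`, `sampleTruth()`, `emitBinCounts()`,
`simulateFeatures()`) emulates the statistical structure of a real
198-pregnancy twin NIPT cohort:

* **Composition** (default `defaultClassMix()`): 112 dichorionic (29 FF /
  46 FM / 37 MM) and 86 monochorionic (50 FF / 36 MM) pregnancies, allocated
  by largest remainder so integral mixes give exact counts.
* **Fetal fraction**: truncated Normal(12.08, 3.50)% on [3.5, 25]%, drawn by
  inverse CDF. The truncation brackets the observed 5.4–23.5% range with
  margin; the truncated mean (12.15%) and SD (3.41%) remain within 0.2
  points of the nominal values.
* **Shedding**: the co-twin ratio is log-uniform on [0.5, 2] (symmetric on
  the log scale, so neither twin is systematically favoured), giving twin A
  the share `r/(1+r)`. For mixed pairs the male is twin B by convention.
* **Frequencies**: `normY = 4.894e-5 + 3.2146e-3 * (male ff sum)/2`, with
  the slope calibrated from the MM group mean `2.431e-4` at the mean fetal
  fraction (`(2.431e-4 - 4.894e-5)/(0.1208/2)`); the implied FM mean
  `1.460e-4` sits within 2.3% of the observed `1.428e-4`, a consistency
  check on the linearity assumption. `normX` falls from `4.973e-2` with
  slope `6.0596e-2`, calibrated the same way.
* **Residual biological noise** is *multiplicative* per class: the noise SD
  scales with the expected frequency, so low-fetal-fraction samples are
  proportionally quieter and the strata remain separable at low ff, as the
  real cohort was (all monochorionic samples correct; the lowest observed
  ff, 5.4% in male twins, correctly classified). An additive model with the
  same cohort-level SDs would let low-ff MM samples collapse onto the FF
  mismapping floor, a failure mode the real data do not show. The
  coefficients of variation are the quadrature remainders of the observed
  group SDs after removing fetal-fraction-driven variance, divided by the
  class means (normY: FF 0.066, FM 0, MM 0.181 — for FM the shedding split
  plus ff spread already induce slightly more spread than observed, so its
  residual is zero; normX: FF 0.0096, FM 0.0074, MM 0.0236). A 5,000-sample
  check reproduces the target group statistics (e.g. MM normY
  2.42e-4 ± 7.08e-5 against 2.431e-4 ± 7.137e-5).
* **Counts**: per-sample depth is log-normal with mean 16,198,687 reads and
  CV 10% (the reference reports only the mean; a 10% CV is a typical
  between-library spread for shallow WGS). Bin-level counts are Poisson
  around expectations that apportion autosomal mass by chromosome length and
  modulate bins by a smooth unimodal multiplicative GC response whose
  per-sample amplitude is uniform in ±`gcBiasAmplitude` (default 0.15),
  globally renormalized to the sample's depth. `countNoise = "expected"`
  replaces Poisson draws by largest-remainder integer allocation, exact to
  about one read per chromosome.
* **Bin map**: deterministic 50 kb bins over GRCh37-length chromosomes with
  synthetic per-bin GC (chromosome base GC plus smooth waves);
  `genomeScale` shrinks all chromosomes proportionally for fast tests
  without changing any frequency.

What the generator does **not** emulate: aneuploid fetuses, maternal
copy-number variants and X-mosaicism, vanishing twins, mappability and
blacklist structure, GC bias shapes beyond a smooth unimodal curve, and any
correlation between fetal fraction and sequencing depth. Tests passing on
synthetic cohorts therefore validate the statistical machinery and the
calibration targets, not robustness to those real-data artifacts.

## Normalization

GC correction fits a loess trend (span 0.75, degree 2, direct surface) of
count versus GC on autosomal bins only — chrY is mismapping-dominated and
chrX carries the signal being measured — with bin-length weights and one
round of trimming beyond 3 MADs; every bin is divided by the trend at its
(support-clamped) GC and the table rescaled to preserve the total count
exactly. Correction happens *before* aggregation to chromosome frequencies;
the reverse order is defensible but correcting first lets the trend see
within-chromosome GC variation. Degenerate inputs (all-zero tables, fewer
than 100 positive autosomal bins, missing sex chromosomes) are errors, and a
constant-GC table passes through unchanged.

## Numerical choices

* **Ridge penalty** default `1e-6` on standardized covariates (never on the
  intercept). FF-vs-male separation is perfect whenever fetal fraction is
  moderate, so plain maximum likelihood diverges; the tiny ridge makes the
  optimum finite without measurably moving probabilities elsewhere. This is
  a deliberate deviation from unpenalized fitting.
* **Optimizer**: damped Newton (IRLS direction, step halved until the
  penalized objective improves), converged at gradient max-norm `< 1e-8`,
  capped at 100 iterations with a warning (the capped iterate is still a
  valid predictor). Deterministic: zero initialization, no randomness, so
  permuting training rows changes coefficients only at floating-point
  order-of-summation level.
* **Standardization**: covariates are centred/scaled by training mean/SD
  internally; stored coefficients are back-transformed to the original
  scale, so serialized models are scale-free.
* **Decision rules**: step one calls FF at `P(FF) >= 0.5`; multinomial and
  step-two decisions are probability argmax with first-listed-class
  tie-break (ties have measure zero with continuous covariates).
* **Line fits**: `stats::lm`; residual SD is RMS (no df adjustment) since it
  parameterizes a band, not a test. Parallel lines (slope difference
  `<= 1e-12`) have no intersection and error out, as do classes with fewer
  than 3 rows or constant fetal fraction.

## Problem sizes

The test suite and the acceptance script work at the cohort's own scale
where that is cheap (LOOCV on 198-sample cohorts, ten seeds; ~1.5 s per
cohort) and at reduced scale where only the machinery is under test
(bin-level simulations use `genomeScale = 0.01`–`0.02`, i.e. ~600–1,200
bins; distributional checks use 2,000–10,000 draws). These sizes are the
package's own choices for a comfortably fast default run.

## Known limitations

* Fetal-fraction estimation is not implemented; real-data users must supply
  it (`fetal_fraction_percent` in the sample sheet). The default 1-point
  Gaussian estimator noise in synthetic runs is a plausible stand-in, not a
  measured error model.
* Sex-chromosome aneuploidies, mosaicism and vanishing twins are out of
  scope and would confound the classifier exactly as they confound the
  underlying assay.
* The two-step model's FM/MM boundary degrades at low fetal fraction with
  strongly unequal shedding — the same regime the threshold analysis
  flags — and no amount of modelling recovers a male signal that is not in
  the plasma.
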