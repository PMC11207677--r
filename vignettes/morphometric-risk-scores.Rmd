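---
title: "Morphometric risk scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric risk scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Case–control differences in regional brain morphometry are real but small:
meta-analytic Cohen's d values for schizophrenia peak around 0.5 for the
most affected cortical regions, so single-region tests in cohorts of a
hundred subjects are badly underpowered. `mrscore` implements a composite
alternative inspired by polygenic risk scoring: instead of testing regions
one at a time, each subject receives one cumulative score that aggregates
their deviations across all 75 bilaterally averaged regions (34
Desikan–Killiany cortical thicknesses, 34 surface areas, 7 subcortical
volumes), weighted by established meta-analytic effect sizes
$\theta_r$.

For subject $i$ with normalized regional deviations $\chi_{ir}$, the score
is built from the products $p_{ir} = \theta_r \chi_{ir}$ restricted to the
*congruent* set $C_i = \{r : p_{ir} > 0\}$ — regions where the subject
deviates in the same direction as the established group effect. The default
aggregation is the absolute mean congruent product,

$$\phi_i = \Bigl|\; \tfrac{1}{|C_i|} \sum_{r \in C_i} p_{ir} \;\Bigr|,$$

with two alternatives (`sum_over_N`, the congruent sum divided by the
number of scoreable regions, and `raw_sum`, the bare congruent sum)
exposed as first-class modes. The summation-style and mean-style
definitions both appear in the literature on this estimator and cannot be
collapsed into one; we therefore record the mode in every result object and
privilege neither in tests — all three are validated against a brute-force
region-by-region oracle. Ties ($p_{ir} = 0$ exactly) are excluded from
$C_i$, which makes all-zero inputs score 0 rather than being undefined.

## Normalization chain

Raw regional measurements are not comparable across metric classes or
scanners. The pipeline normalizes in three steps, in this order:

1. **Deconfounding.** Each region is residualized by OLS on
   `[1, age, sex, global]`, where the global regressor matches the metric
   class: mean cortical thickness for thickness, total surface area for
   area, ICV for subcortical volume. The fitting population defaults to the
   whole sample (the score measures deviation from the *sample* norm); a
   controls-only option exists because the literature is ambiguous on this
   point, and the choice is recorded in the fitted transform.
2. **z-rescaling** with the fitting population's residual mean and SD, so
   thickness (mm), area (mm²) and volume (mm³) contribute on an equal,
   unitless footing.
3. **Site harmonization** by empirical-Bayes location/scale adjustment
   (ComBat). We implement the parametric Johnson–Li–Rabinovic recipe
   in-package — standardization against the size-weighted grand mean and
   pooled variance, per-site location/scale estimates shrunk toward
   Gaussian / inverse-gamma moment-matched priors by iterative conditional
   estimation (tolerance 1e-6, at most 1000 iterations) — because
   downstream use needs the *fitted model* (standardization constants,
   shrunken per-site effects, hyperparameters) to reapply the identical
   transform to a replication sample; reference implementations return only
   the adjusted matrix. Our output matches `sva::ComBat` to ~1e-7 on
   simulated cohorts, and that cross-check is part of the test suite. A
   `mean_only` mode shrinks locations only. Degenerate priors (no spread
   across regions) collapse to complete shrinkage rather than NaN. ComBat
   shrinkage leaves per-region grand means preserved exactly only in
   balanced/degenerate cases; on realistic data the residual is small but
   not at machine precision, and tests assert accordingly.

Deconfound-then-ComBat is the default order, mirroring the order in which
these steps are usually described; a `combat_first` flag supports
sensitivity analysis. All fitted transforms are serializable and are
applied *unchanged* to replication data (`apply_deconfound()`,
`apply_combat()`); a single-site replication sample leaves the site step as
the identity.

## Weight sets

Four weight sets are derived from two raw per-region effect-size vectors
(schizophrenia and bipolar disorder):

* `pc1_shared` — per-region scores on the first principal component of the
  75×2 centered matrix of the two vectors, computed from the 2×2
  covariance eigendecomposition. "Shared variance" admits several readings;
  PCA over the two centered vectors is the minimal one, and the sign is
  fixed so that the component correlates positively with the schizophrenia
  profile (higher score = more schizophrenia-like). A per-region mean would
  be an alternative reading; it is nearly collinear with PC1 when the two
  profiles correlate positively, as they do here.
* `scz_unique` / `bd_unique` — residuals of one vector regressed on the
  other (with intercept by default; a no-intercept flag exists). The
  residualized vector is exactly uncorrelated with the other profile.
* `h0` — unit weights for every region, the negative control. We read the
  "no weights" control as $\theta_r = 1$ under the same congruency rule
  rather than dropping the weighting term altogether, because it keeps the
  score's functional form (and hence its sampling distribution) comparable;
  the literal-product alternative is the same thing up to the congruency
  set, which unit weights already determine.

The package bundles *synthetic* schizophrenia-like and bipolar-like weight
tables (hand-authored, with the field-typical shape: diffuse cortical
thinning strongest in temporal cortex, small area effects, mixed
subcortical effects). They exist so every stage is exercisable without
redistributing meta-analytic tables; real weights are supplied by the user
as two-column CSVs.

## Inference

* **Group models.** Each outcome (a score, or a single region) is
  z-rescaled and regressed on diagnostic status with age, sex, IQ, ICV,
  mean thickness and mean area as fixed covariates. Site enters as a random
  intercept (REML, Satterthwaite df via `lmerTest`), as fixed dummies, or
  not at all (single-site replication). A singular random-intercept fit —
  common after harmonization, which is designed to remove exactly that
  variance — falls back to fixed dummies with a warning. Cohen's d is
  derived from the adjusted contrast as $d = 2t/\sqrt{df}$; the convention
  is recorded and a raw-group d helper (`cohens_d()`) exists.
* **Outlier labeling.** One non-iterative pass of the 1.5×IQR labeling rule
  (type-7 quantiles) on the outcome, applied per model.
* **Multiplicity.** Benjamini–Hochberg step-up via `p.adjust`, validated
  against an all-cutoffs enumeration. Post-hoc pairwise diagnosis
  contrasts come from estimated marginal means with FDR across the
  contrasts.
* **Competing scores.** Whether the weighted score relates to diagnosis
  more strongly than the unit-weight control is tested with the
  Hotelling–Williams/Steiger t for two dependent overlapping correlations
  (df = n − 3), one-sided where the direction is prespecified.
* **Composite vs regional effects.** The composite's |SMD| is standardized
  against the mean and SD of the 75 regional |SMD|s,
  $z = (|d_{MRS}| - \overline{|d_{ROI}|}) / \mathrm{sd}(|d_{ROI}|)$, with a
  normal p. No canonical formula exists for this comparison; this
  mean/SD reconstruction is the package's documented choice, and absolute
  values are used so reductions and enlargements compare on one scale.
* **Spatial nulls.** Profile correlations between an estimated per-region
  SMD map and a weight map are tested against
  autocorrelation-preserving nulls: uniform random 3-D rotations of
  approximate spherical parcel centroids with greedy one-to-one
  nearest-centroid reassignment for the 34-parcel cortical maps
  (two-sided, `(1 + #{|r*| ≥ |r|})/(1 + n)`), and exhaustive enumeration of
  all 5040 label permutations for the 7 subcortical volumes. The bundled
  centroid table is an approximate, hand-authored embedding (unit-sphere
  projections of standard anatomical directions), not a FreeSurfer sphere
  registration; it is clearly labelled, overridable by a user file, and
  sufficient for the parcel-level test, whose calibration is verified by
  simulation rather than assumed. Default 10 000 rotations.
* **Power.** Two-sample t-test power through the noncentral t distribution
  with $\lambda = d\sqrt{n_1 n_2/(n_1+n_2)}$, checked against a 10⁶-draw
  Monte-Carlo oracle.
* **Classification.** A single-predictor logistic model fitted on discovery
  scores is applied unchanged to replication scores (the
  out-of-distribution contract); accuracy is reported with a
  Clopper–Pearson exact binomial interval. The feature set is the single
  SCZ-unique score by default; the upstream literature does not state
  whether covariates were included, and adding them is left to the user.

## The synthetic cohort generator

`simulate_cohort()` draws covariates and global measures per diagnostic
group, builds each region as baseline + global coupling + linear
age/sex effects + independent Gaussian residual, injects the diagnosis
effect *on the residual scale* (so the true per-region SMD vector is exactly
the configured `effect_profile`), and finally contaminates by site
(`value ← scale · value + shift`). `emulate_table1()` returns
configurations whose group sizes, age, sex, IQ and global-measure
distributions match the two published samples the method was demonstrated
on: a four-site discovery cohort (23 bipolar / 47 control /
54 schizophrenia, sites of 60/17/33/14) and a single-site replication
cohort (24 control / 45 schizophrenia). Per-region baselines and SDs are
free defaults at plausible FreeSurfer scales, since the descriptive tables
report only global means; site shifts/scales are mild
(±0.15 additive, ±4% multiplicative) so that harmonization has real work
to do without dominating the signal.

What the generator deliberately does **not** emulate: correlated residual
noise across regions (regions are independent after the global factor —
the simplest model satisfying every assumption the linear pipeline makes;
a correlated-noise option is a config extension), nonlinear age effects,
longitudinal structure, and any coupling of IQ to brain structure (IQ is a
covariate only). Passing tests therefore demonstrate correctness of the
machinery and calibration of the inference under these assumptions, not
that real cortical data meet them. The independence assumption matters
for one published-style claim in particular: with 75 independently noisy
regional SMD estimates (sampling SD ≈ 2/√df ≈ 0.19 at n = 124), the
*maximum* regional |SMD| is typically 0.55–0.65 even when every true
regional effect is below 0.37, so a composite with true adjusted d = 0.6
outranks all 75 regions in only roughly half of simulated replicates.
In real data, where residuals correlate across regions and the effective
number of independent regional draws is much smaller, composite-over-max
dominance is easier to achieve. The test suite states the dominance
property at its literature-derived threshold and we report the measured
rate rather than restating the threshold to fit it.

## Calibrated effect profiles

Simulation studies use a diffuse true profile proportional to a weight
vector, `c · θ`, with `c` chosen by `calibrate_effect_profile()` so that
the *composite* score reaches a target SMD (default 0.6). The target is
measured on the covariate-adjusted scale the group model reports, using a
scaled-up cohort (40× group sizes, ≈ 5000 subjects) with common random
numbers and root finding: the generator couples age, IQ and the global
measures to diagnosis exactly as the published descriptive tables do, and
that coupling inflates the adjusted contrast's standard error, so a
profile calibrated on the raw score scale would undershoot the adjusted
target by ~18% and with it every downstream power statement. A `raw`
measure is available for uncontaminated designs.

## Numerical choices and degenerate inputs

Quantiles use the type-7 linear-interpolation convention. Permutation
p-values use the `(1+)/(1+n)` estimator except in exhaustive mode, where
the p is exact. The spin test's greedy assignment breaks distance ties by
parcel index (stable ordering). The Williams test returns t = 0 for
(anti)identical scores with equal correlations and refuses other |r| = 1
degeneracies. Constant-score logistic fits predict flat probabilities
rather than erroring. All simulation entry points take explicit integer
seeds, restore the caller's RNG state, and derive sub-stream seeds by
fixed offsets, so every artifact is reproducible from `(config, seed)`.

Problem sizes used by the shipped validation suite: 500 replicates for the
null-calibration and power/dominance studies at the published cohort size
(47/77), 200 runs × 1000 rotations for spin-test calibration, 5000
simulations for the Williams-test calibration, and 2000/2000 subjects for
profile recovery — sizes at which the binomial error on a rate in
[0.03, 0.07] is about ±0.01.

## Known limitations

Parcel-level spin tests are coarser than vertex-level rotation nulls and
the bundled geometry is approximate. The generator's independence
assumptions are stated above. Scores are only comparable within a cohort
processed by one protocol; applying a discovery-fitted transform to data
from an unseen site requires that site to be treated as new (no ComBat
reapplication). No vertex-wise scoring, multimodal fusion, Bayesian or
longitudinal variants are provided.
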