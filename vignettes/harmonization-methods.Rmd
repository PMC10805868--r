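---
title: "Leakage-safe harmonization of multisite neuroimaging features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leakage-safe harmonization of multisite neuroimaging features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msCombat)
```

## The problem

Pooling tabular MRI-derived features (regional cortical thickness, fractal
dimension, volumes, ...) across acquisition sites introduces non-biological
variability: scanner vendor, field strength, coil, protocol and processing
version all leave a mark on the features. ComBat-style harmonization removes
additive and multiplicative site effects while preserving covariate-driven
biological variation. msCombat implements the model together with three
pieces of machinery built around it:

1. a **harmonizer transformer** with a strict fit/transform contract, so the
   harmonization step can live inside a cross-validated machine-learning
   pipeline and is estimated on training folds only;
2. an **efficacy assessment** that decides, with significance tests, whether
   harmonization *removed* or merely *reduced* the site effect;
3. a **simulation and leakage experiment** that quantifies how much fitting
   ComBat on all data before splitting inflates apparent performance.

A 3D box-counting **fractal dimension** estimator with automated
scaling-window selection is included as the feature extractor for structural
complexity features.

## The harmonization model

For site $i$, subject $j$ and feature $f$, observed features are modeled as

$$ y_{ijf} = f_f(X_{ij}) + \gamma_{if} + \delta_{if}\,\varepsilon_{ijf}, $$

where $f_f$ captures the biological covariates (age, sex), $\gamma_{if}$ is
the additive and $\delta_{if}$ the multiplicative site effect, and
$\varepsilon_{ijf}$ are mean-zero residuals. `fitCombat()` proceeds in the
standard location/scale fashion:

* **Covariate model.** Each feature is regressed on site indicators plus a
  covariate design: smooth terms (age) enter through a natural cubic spline
  basis with `splineDf = 5` and interior knots at training quantiles; linear
  terms (sex) enter as dummies. A fixed spline basis was chosen over a
  penalized smoother because it is deterministic, serializable, and cheap to
  re-evaluate on new subjects; out-of-range covariate values at transform
  time are clamped to the training boundary (the spline is linear beyond the
  boundary knots, so clamping is a mild, monotone extrapolation).
* **Standardization.** Features are centred on the precision-weighted grand
  site intercept plus the covariate prediction, and scaled by the pooled
  residual SD. No designated reference site is used.
* **Empirical Bayes.** Per-site locations get a normal prior, per-site
  squared scales an inverse-gamma prior; hyperparameters come from the
  method of moments across features, and the conditional updates are
  iterated to a relative tolerance of 1e-6 (at most 100 iterations).
  Parametric EB is the default and only mode; with 11-feature panels the
  shrinkage stabilizes small-site estimates noticeably.

`applyCombat()` inverts the standardization using **stored parameters
only**: subtract the EB site location, divide by the EB site scale, restore
the covariate prediction. Applying a model to data from a site it never saw
is an error by design — inventing parameters for a new site would silently
break the leakage guarantees.

The unit tests cross-check the whole fit/apply path against an independent
reference implementation (`sva::ComBat`) on a toy instance with a linear
covariate; agreement is at the 1e-8 level, limited only by the two
implementations' different EB stopping rules.

## The harmonizer transformer

`harmonizer(spec)` packages the model behind the estimator convention used
by pipeline frameworks: parameters are declared at construction, `fit()`
sees training data and returns a *new* fitted object (the prototype stays
unfitted, so one prototype can be reused across folds), and
`transformTable()` maps any table row-by-row using the stored parameters.
No statistic of the incoming table influences the mapping — this is the
property that makes cross-validation honest, and it is what the tests
verify: perturbing one subject changes only that subject's output, and a
transform with stored parameters provably differs from a model refit on
train + test.

By default the transformed table still carries its metadata columns (site,
age, sex) for bookkeeping, but downstream estimators in this package only
ever see `featureMatrix()`, so the site label cannot leak into prediction
through the feature matrix.

## Quantifying the site effect

Three complementary views, in increasing strictness:

* `ancovaSiteEffect()` fits `feature ~ site + age + age² + sex` per feature
  and reports the partial $\eta^2 = SS_{site} / (SS_{site} + SS_{res})$ of
  the site factor, with marginal (Type II) sums of squares via `car::Anova`.
* `repeatedCV()` predicts the site from the features with a gradient-boosted
  tree classifier (100 trees, depth 3, learning rate 0.1 — the historical
  default hyperparameters, deliberately not tuned) under repeated
  site-stratified 5-fold CV, summarized by balanced accuracy (chance $1/k$).
* `assessEfficacy()` runs the two-step verdict. Step 1: an
  **age-group-constrained permutation test** — site labels are shuffled only
  within 5-year age bins, so the null preserves the age structure of site
  membership (sites differ systematically in age; unconstrained shuffling
  would test the wrong null). 5000 permutations by default, one stratified
  5-fold CV per permutation, and the permutation-inclusive estimator
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, which is valid for
  any $B$. If $p \ge 0.05$: the site effect is **removed**. Step 2
  (otherwise): a one-sided Wilcoxon signed-rank test on paired repetitions
  decides whether harmonization at least **reduced** site predictability.

Design choices worth stating: age bins are anchored at the minimum age and
singleton bins are merged with their nearest neighbour; the null statistic
uses a single CV run per permutation (thousands of repeated-CV runs per
permutation would be computationally indefensible and add nothing to the
null's validity); and the p-value uses the add-one correction because the
plain proportion can be anti-conservative at small $B$.

## The simulator

`simulateMultisite()` draws features from

$$ y_{ijf} = \alpha_f + \beta_1 x_{ij} + \beta_2 x_{ij}^2 + \gamma_{if}
   + \delta_{if}\,\varepsilon_{ijf}, $$

with ages uniform on [20, 90], $\beta_1 = -9\times10^{-4}$,
$\beta_2 = -5\times10^{-5}$ (a gently decelerating age decline typical of
cortical features), additive site effects $\gamma_{if} \sim N(0, 0.1^2)$,
and multiplicative site effects drawn per site-feature from an
inverse-gamma distribution with site-specific shape and scale 50 (shapes
{46, 51, 56} for 3 sites, {40, 42, ..., 58} for 10, and
{10, 12, ..., 40, 41, ..., 50, 52, ..., 70} for 36 — smaller shape = noisier
site). Location and scale effects are drawn independently per site-feature
pair; the alternative reading (one $\gamma_i$ shared by all features of a
site) is stricter than anything the harmonization model assumes, so the
per-feature choice is the conservative one to validate against.

Two generator constants are not pinned by the study design and were fixed
once, on realism grounds:

* `V = 11` features — one per region in a hemisphere/lobe-level cortical
  parcellation (entire cortex, left/right hemispheres, left/right frontal,
  temporal, parietal, occipital lobes).
* `noiseSD = 0.1` — the residual scale of $\varepsilon$. Regional cortical
  thickness in healthy adults has a between-subject residual SD of roughly
  0.1 mm after age/sex adjustment, and this puts the generator's additive
  site effects (SD 0.1) on the same order as the residual spread — the
  regime real multisite panels sit in. A standard-normal residual would make the features an
  order of magnitude noisier than any real cortical panel and would erase
  the age signal entirely (the age trend spans ~0.45 units over the
  lifespan); with SD 0.1 the simulated panels support age prediction at
  mid-single-digit MAEs, as real cortical panels do. CT-like and FD-like
  panels differ only in baseline
  ($\alpha$ = 2.5 vs 2.6), which site/age prediction by trees is invariant
  to.

One subtlety of the generator worth knowing: post-harmonization site
predictability is not invariant to the ratio of site-shift SD to residual
SD. The empirical-Bayes shrinkage weight grows with that ratio, so with
strong shifts (the default: shifts comparable to the residual spread) a
larger share of the site-parameter estimation error survives into
harmonized data, and arms whose test data carry that shared estimation
error — the external arm in particular — sit measurably above chance even
though the true site effects are gone. This is a property of
location/scale EB harmonization itself, not a defect of the transformer.

What the simulator does *not* emulate: correlated features (no covariance
site effects), non-uniform age distributions across sites, missing data,
and site-varying sample sizes. Passing tests on simulated data therefore
validate the machinery, not the harder epidemiological realities of in vivo
multisite samples — in particular, age-disjoint sites remain intrinsically
hard for any covariate-preserving harmonization.

## The leakage experiment

`runLeakageExperiment()` implements a three-arm protocol per repetition:
simulate, split 50/50 (site-stratified) into a *data set* and an *external
test set*, then

* **external**: fit ComBat on a random site-stratified 80% of the data set
  (80% matches the training-fold share of a 5-fold CV, so all arms estimate
  harmonization from the same number of subjects), harmonize both halves,
  train on the data set, score on the external set;
* **not-leaked**: a stratified 10×5-fold CV on the data set with the
  harmonizer inside the pipeline;
* **leaked**: harmonize the whole data set once, then the same CV with the
  same fold assignments.

All arms of a repetition consume identical simulated data, the same
hold-out and the same folds, which makes the arms paired; the summary tests
are therefore one-tailed *paired* t-tests (internal arm better than
external, i.e. lower balanced accuracy for the site task — leakage makes
harmonization look more complete than it is — and lower MAE for the age
task), Bonferroni-corrected over the two internal arms, plus Cohen's
$d = (\bar x_e - \bar x_i)/s_{e-i}$.

A counter-intuitive but robust finding of this protocol: the leaked arm
falls *below* chance on the site task, and it does so even when the
simulation injects no site effect at all. Fitting ComBat on the whole data
set removes the *observed* per-site means — part of which is sampling
noise — so the CV test rows, having contributed to the very means that
were subtracted, end up anti-correlated with their own site label.
Leakage does not merely inflate apparent harmonization efficacy; it
manufactures it out of noise.

Per-repetition CV performance is pooled over the folds of each 5-fold run
and averaged over the 10 repeats; fold metrics and pooled metrics differ
negligibly at these sizes, and pooling keeps per-class recalls defined even
when a site has very few subjects in one fold.

## Fractal dimension

`boxCount()` overlays grids of cubes of side $s = 2^k$, $k = 0..8$, and
counts occupied boxes. Twenty random grid offsets are averaged per scale to
suppress the systematic influence of grid placement. Offsets act
*periodically* within the padded power-of-two cube: the grid conceptually
tiles all of space, so a structure that exactly tiles the boxes (a filled
cube, a one-voxel-thick plane) yields the identical count at every offset.
The non-periodic alternative (zero-padding and letting shifted boxes spill
past the volume) systematically inflates the counts at the coarsest scales
— a 256-wide plane straddles two boxes per axis at $s = 256$ — which biases
the fitted slope low by 5–10% on reference solids; the periodic convention
removes that bias and makes the estimator exactly translation-invariant.

`selectScalingWindow()` fits $\log_2 N$ vs $\log_2 s$ over every contiguous
window of at least 4 scales and picks the window with the maximal adjusted
$R^2$ rounded to 2 decimals; ties go to the widest window, equal-width ties
to the finest scales. Degenerate windows with constant $N$ are treated as
perfect fits with slope 0. The fractal dimension is the absolute slope in
the selected window; reference solids recover their known dimensions
(plane 2, cube 3, level-5 Menger sponge $\log 20/\log 3 \approx 2.727$)
within 0.05 at the defaults.

## Estimators, seeds and problem sizes

The prediction engine defaults to gradient-boosted trees (the estimator
family whose historical defaults the study design pins: 100 trees, depth 3,
learning rate 0.1, no subsampling), run single-threaded with a fixed seed
per repetition so every run is exactly reproducible; the histogram split
finder with 64 bins is used, which at a few hundred training rows is
statistically equivalent to exact splits and several times faster.
Estimators are pluggable: any list with `fit(X, y, seed)`/`predict(model,
X)` works, and `ldaEstimator()` provides a fast linear classifier used for
estimator-agnostic properties such as permutation p-value calibration,
where thousands of fits are needed and only the validity of the permutation
machinery — not the estimator's accuracy — is under test.

The package's own validation runs the full protocol at desk
scales: 25 outer repetitions for 3-site configurations, 10 for 36-site
ones, 199-permutation calibration over 200 null datasets, and reference
solids up to $256^3$ voxels. Larger runs (100 repetitions, 5000
permutations) are the function defaults and scale linearly.

## Known limitations

* New sites cannot be transformed; there is deliberately no
  transfer-learning fallback.
* Only parametric EB priors are implemented (no nonparametric mode).
* Covariance (correlated-feature) site effects are neither simulated nor
  harmonized.
* The Bhattacharyya overlap of age distributions depends on a binning
  convention (shared 1-year bins anchored at the floored pooled minimum);
  overlap values computed elsewhere under an unknown binning can differ in
  the second decimal.
* Wilcoxon p-values use the normal approximation (ties in balanced
  accuracies across repetitions are common, so exact p-values are not
  generally available).
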