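---
title: "Single-plant field omics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-plant field omics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldomics)
```

## The problem

A field trial in which every plant is molecularly profiled produces
feature-by-plant matrices whose between-plant variation mixes (i) biology of
interest, (ii) systematic group effects — sequencing batch, day of harvest
(DOH), genetic subgroup — and (iii) spatial autocorrelation: plants that grow
close together share soil, moisture and light micro-environment, so their
profiles correlate as a function of field distance. Treating the plants as
independent replicates then inflates correlation and association
significance. `fieldomics` puts the spatial correlation into the error model
of every fit instead of ignoring it.

## The spatial error model

Every per-feature model in the package has the form `y = Xβ + ε` with
`ε ~ N(0, σ²C)` and

`C = n·I + (1 − n)·K(r)`

where `K` is a unit-diagonal spatial correlation kernel. Two kernels are
used, matching their roles:

* **spherical** (`corSpher(d; r) = 1 − 1.5(d/r) + 0.5(d/r)³` for `d < r`,
  else 0) for molecular features and gene-pair correlations. It reaches
  exactly zero at the range, so `r` is interpretable as the distance at
  which plants become independent; it is positive semi-definite in up to
  three spatial dimensions.
* **rational quadratic** (`corRatio(d; r) = 1/(1 + (d/r)²)`) for phenotype
  regressions, where its slower decay gives stable in-field range estimates.

The nugget `n ∈ [0, 1]` is the i.i.d. fraction of the residual variance;
`1 − n` is spatially structured. `n = 1` or `r = 0` collapses the model to
ordinary least squares — this boundary is handled explicitly (below).

### REML estimation

The fixed effects and `σ` are profiled out analytically, leaving a
two-parameter restricted likelihood over `(n, r)`. That surface is flat near
the i.i.d. boundary and can be multimodal when the spatial signal is weak, so
the optimizer is deliberately global-then-local:

1. **Grid stage.** `r` on a log-spaced grid from the minimum plant spacing to
   twice the field diagonal (15 points by default); for each grid range the
   kernel matrix is eigendecomposed **once** and cached, making the
   per-feature cost of any nugget value O(N·p). The nugget is optimized per
   range by a 1-D search seeded from a coarse grid (0.05–0.95).
2. **Refinement.** Golden-section search over `log r` between the best grid
   neighbours, with the inner 1-D nugget optimization repeated at every
   probed range (a bounded number of eigendecompositions, 12 by default).

The cache is shared across all features fitted on one layout, which is what
makes residualizing thousands of features and fitting all gene pairs of a
network tractable.

The REML log-likelihood normalization was verified against `nlme::gls`
(evaluating the package's restricted likelihood at `gls`'s fitted parameters
reproduces `logLik(gls)` to machine precision), and on multimodal test cases
the grid-then-refine search finds optima at least as good as `gls`.

### The OLS fallback

The reference analysis falls back to ordinary least squares when the spatial
fit does not converge (nugget near 1 or range near 0). Here the fallback
fires when:

* the interior optimum improves the restricted log-likelihood over the
  i.i.d. submodel by less than `min_ll_gain` (default `1e-4`) — i.e. no real
  spatial optimum was found;
* the fitted nugget exceeds 0.999; or
* the fitted range is below half the minimum plant spacing (at which point
  the spherical kernel is identically zero between plants and the model *is*
  OLS).

For pairs/features that reduce this way the coefficient and p-value equal
the closed-form OLS (Pearson, for z-scored no-intercept pairs) values
exactly, which the tests assert at 1e-6. Note that a fit retaining a weak
interior spatial optimum is *not* numerically equal to OLS — equality holds
exactly for, and only for, the reduced fits, which is also how the reference
analysis describes it.

Wald t statistics with `N − p` degrees of freedom give the fixed-effect
p-values; the reference analysis does not state its test, and at `N − p ≥
50` the choice is immaterial.

### Variance decomposition

With `f = β_b x_b + β_d x_d + β_s x_s`, the package reports
`R²_fix = var(f)/(var(f) + σ²)`, per-effect analogues, and
`R²_ε = 1 − R²_fix`, split into `R²_cov = (1 − n)R²_ε` (spatial) and
`R²_iid = n·R²_ε`. The two identities `R²_fix + R²_ε = 1` and
`R²_cov + R²_iid = R²_ε` hold exactly by construction and are asserted on
every fit; the per-effect shares only sum to `R²_fix` approximately because
the binary covariates are not orthogonal in a finite sample.

## Preprocessing

Counts: genes are kept when they reach 5 counts per million (against raw
library sizes) in at least one sample; libraries are scaled by
median-of-ratios size factors (geometric-mean pseudo-reference over genes
positive in all samples — re-implemented rather than imported, since the
procedure is five lines and the contract demands exact control of the
reference set); log2 after adding half the smallest nonzero value (`0.5δ`),
stored so the transform inverts exactly (back-transformed matrices have
minimum exactly zero, which the CV computation relies on).

Metabolites: log2, then iterative two-sided Grubbs outlier masking at
α = 0.01 per test (the reference analysis does not say whether α is
adjusted; per-test is implemented as written, with at most `n − 3` removals
per metabolite), removal of metabolites missing in more than half the
samples, then imputation, then quantile normalization (ties get the mean of
the quantile values their ranks span, making the procedure idempotent on
tie-free data).

Imputation is iterative truncated-SVD completion (default rank
`min(n_samples − 2, 48)`, convergence when the imputed entries change by
less than 1e-6 relative, error after 500 iterations). This replaces Bayesian
PCA: both fill missing entries from a low-rank linear reconstruction;
BPCA's variational machinery is an external algorithm with no stated
equations in the source analysis. Convergence is fast when the data really
are low-rank plus noise and slow when the target rank approaches the matrix
dimension — the error message reports the last relative change so users can
lower the rank.

## Spatial screening, clustering, variability

Moran's I uses inverse-distance weights, left row-unstandardized by default
with a `row_standardize` option (the commonly used implementation
row-normalizes; the oracle tests match it under that option). P-values come
from the normal approximation with the randomization (kurtosis-corrected)
variance, two-sided, with a permutation alternative; BH adjustment is a
direct step-up implementation tested against `p.adjust`.

Features passing the Moran q-threshold (0.01) are z-scored and clustered
with `hclust(ward.D2)`. The reference analysis used fixed cluster counts
without stating the cut rule; here `k` is user-specified, defaulting to the
`k ∈ 2..20` maximizing the mean silhouette width — a standard, deterministic
choice.

Variability: CVs (sample SD over mean; the denominator convention is not
stated in the source, `n − 1` is used) are computed on back-transformed
linear-scale data. The transcript trend `CV² = a/mean + b` is fitted by a
gamma GLM with identity link after dropping the 5% lowest-mean features
(positivity-guarded OLS start values, nonlinear least squares fallback);
metabolites use OLS on log10 CV² vs log10 mean. `normCV =
log2(CV²/trend(mean))`; the top/bottom 10% by decreasing normCV are flagged,
ties broken by feature id so the flagged sets have exactly
`floor(0.1·n)` members. The 5% exclusion is applied before ranking, matching
the source's description of the ranked list.

## Co-expression network and function prediction

All gene pairs are fitted as `y = βx + ε` on z-scored profiles with
spherical-covariance errors; Bonferroni correction uses the number of pairs
tested (the alternative — counting only successfully fitted pairs — differs
only when pair fits fail, which is not the case here). Edges require
corrected p ≤ 0.01. The fraction of pairs retaining a nonzero range is
reported (`spatial_fraction`) but is a data property, not a target.
Comparison networks are built with plain Pearson correlation
(`spatial = FALSE`) and thresholded to a fixed edge count with a fully
deterministic order (p, then |β|, then pair id).

Function prediction is hypergeometric enrichment of each term among a
gene's **direct** neighbors against the annotated-network-gene background,
with the focal gene excluded from its own neighborhood, BH adjustment across
all gene-term tests of one network (network-wide q-values are what the
benchmark thresholds refer to), and true-path-propagated annotations.
Predictions of already-annotated terms count as true positives for scoring;
"novel" predictions are reported separately.

The relative-performance classifier compares a focal F-measure curve to an
ensemble over the threshold subrange where the focal network or at least
half the sampled networks have nonzero F. The five labels are decided by
which percentile curve (25/50/75) the focal curve tracks most closely
(RMSD), with the sign of the median deviation separating good from poor;
the quoted criterion defines the classes only by reference, so these
concrete boundaries are this package's rendering and are documented as such.

## Phenotype prediction

Nested cross-validation: 10 outer folds, 4 inner folds for tuning,
selection by mean inner out-of-fold R², winner refitted on the full outer
training set. Elastic nets (glmnet; its `(lambda, alpha)` maps one-to-one
onto the shrinkage/L1-ratio grids of the reference implementation; the
grids — shrinkage `10^(-3..0)` in 7 log steps, L1-ratio
{0.1, 0.3, 0.5, 0.7, 0.9, 1} — are defaults recorded in the output, since
the source states none) and regression random forests (500 trees,
`max_features` grid sqrt/0.33/log2/none, `min_samples_split` 2–5). No
pre-installed forest package exists in the target environment, so the forest
is a compact Rcpp implementation: bootstrap CART with variance-reduction
splits and MDI importances, deterministic given the seed.

Features are z-scored globally before modeling, matching the reference
procedure; a leakage-safe per-fold scaling is available (`zscore` happens
on the full matrix before the fold split — with n ≈ 60 the difference is
small but real, and the global variant is what the reported numbers used).

Permutation p-values `p = (n+1)/(k+1)` re-run the **entire** pipeline,
including hyperparameter tuning, on each permuted phenotype, re-using the
fold structure; a `reduced_grid` option caps the cost for permutation
studies (tuning only the shrinkage path) — validity requires only that true
and permuted fits use the identical procedure. The p-value floor is
`1/(k+1)` and its standard deviation `√(p*(1−p*)/k)`.

## The synthetic world

The generator is first-class, tested code, and its defaults are the stated
conditions of the emulated trial: a 10 × 56 grid (560 plants), 10 cm
within-row spacing (5.6 m rows of 56 plants) and 75 cm between rows. What
the source does not state — it never simulates data — was chosen once:

* **Latent factors:** 3 spherical GP fields, ranges 150/300/600 cm, nugget
  0.2, unit σ. The real spatial scales of micro-environmental factors are
  unknown; these spread from "a few plants" to "most of the field" and are
  placeholders, not estimates.
* **Counts:** Poisson-lognormal (Poisson observation around
  `library_factor · 2^signal`), with a pure lognormal mode for fast exact
  tests.
* **Labels:** batch and DOH assigned by contiguous field blocks (harvesting
  and library preparation happen in batches), SNP subgroup at random; 30% of
  features get N(0, 0.5) log2-scale group effects.
* **Modules:** planted gene modules (≥ 5 genes) load on one factor each and
  share one leaf term of a three-level is_a ontology; a configurable
  fraction of true annotations is withheld as the recall oracle.
* **Metabolite missingness** is completely at random; value-dependent
  missingness is out of scope.

What a green test on this world does **not** establish: realistic count
overdispersion beyond Poisson-lognormal, annotation incompleteness structure
of a real GO corpus, genetic relatedness beyond a binary subgroup, or
anisotropic field gradients. The synthetic benchmarks validate the
machinery — estimator consistency, calibration, recovery of planted
structure — not field-realism.

## Numerical choices and degenerate inputs

* Constant features/profiles are refused (`degenerate-input` errors) or, in
  batch runs, collected per feature without aborting.
* GP sampling adds diagonal jitter (1e-8 of the diagonal) only if the
  Cholesky fails, and errors with diagnostics if it still fails.
* An exactly collinear gene pair has zero residual variance; the residual
  variance is clamped at 1e-300 so the fit stays defined (β = 1, p = 0).
* Tie-breaks are deterministic everywhere (edge thresholding, variability
  flags), so identical seeds give byte-identical pipeline outputs.

## Known limitations

* The pair-correlation model is asymmetric; for strongly spatially
  confounded pairs the x→y and y→x REML optima genuinely differ (the
  reference gls implementation shows the same), so |β| symmetry holds
  exactly only for pairs reducing to the i.i.d. route.
* O(G²) pair fitting is feasible to a few hundred genes on one CPU; a
  Pearson prefilter (off by default) trades exactness for scale.
* Only the spherical (expression) and rational quadratic (phenotype)
  kernels are implemented; kinship/random-effect terms are out of scope.
* The relative-performance class boundaries are this package's concrete
  definition of a criterion its source defines only by citation.
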