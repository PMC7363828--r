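---
title: "Objective-specific sparse CCA: model, tuning and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective-specific sparse CCA: model, tuning and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscca)
```

## The model

Imaging genetics asks how genetic variation relates to brain structure, and
— when a clinical quantity such as age at onset (AAO) is the scientific
objective — which imaging-genetic associations are actually relevant to
that objective. Plain sparse canonical correlation analysis (sparse CCA)
finds loading vectors $u$ (imaging) and $v$ (genetics) maximizing
$\mathrm{corr}(Xu, Yv)$, but the selected features need not relate to the
clinical target at all. The model implemented here adds the target as a
third, one-dimensional block $Z$ and maximizes all three pairwise
associations at once. Because $Z$ is a single column, its loading
degenerates to a fixed positive scalar $w$, and the fitting problem becomes

$$
\min_{u,\,v}\; -u^\top X^\top Y v \;-\; w\, v^\top Y^\top Z
\;-\; w\, Z^\top X u \;+\; \lambda_u \lVert u\rVert_1
\;+\; \lambda_v \lVert v\rVert_1,
\qquad \lVert u\rVert_2 \le 1,\; \lVert v\rVert_2 \le 1 .
$$

All blocks are column-standardized before fitting, so the bilinear terms
are (scaled) sums of correlations. The $\ell_1$ penalties produce exact
zeros; the non-zero positions of $u$ and $v$ *are* the selected imaging
regions and variants.

With one block fixed the problem in the other block is
$\min_u -g^\top u + \lambda\lVert u\rVert_1$ on the unit ball with
$g = X^\top Y v + w X^\top Z$, whose closed-form solution is
soft-threshold-then-normalize, $S(g,\lambda)/\lVert S(g,\lambda)\rVert_2$
(the penalized-matrix-decomposition update). The solver alternates these
two closed-form updates; every update is an exact block minimization, so
the objective is non-increasing along the trajectory, which the result
object records.

### Initialization and multi-start

The objective is bi-convex, not jointly convex: a single start can settle
in a block-wise fixed point that is not the global optimum (we observed
gaps up to 0.4 on small random instances). The deterministic default
therefore runs a small fixed set of starts — the leading right singular
vector of $X^\top Y$ in both orientations, the normalized target gradient
$Y^\top Z$, a target-driven composite direction, and the zero corner
(optimal under heavy shrinkage) — and keeps the run with the lowest final
objective. Everything is deterministic; a seeded random initialization is
available for robustness experiments. On 50 random small instances this
multi-start scheme matches a 20,000-restart derivative-free reference
search (`oscca_oracle`, which random-samples the unit spheres and polishes
the best candidates with Nelder–Mead) to about $10^{-12}$.

Sign convention: $(u, v) \mapsto (-u, -v)$ leaves the two-block part of
the objective unchanged (it is exactly invariant when $w = 0$), so the
reported solution is oriented to have
$\mathrm{corr}(Xu, Z) \ge 0$ whenever $Xu$ is non-constant.

### Parameters that matter

* `lambda_u`, `lambda_v` — the $\ell_1$ soft-threshold levels
  (dimension: same scale as the gradient, i.e. $n \times$ correlation).
  Larger means sparser. Tuned by default.
* `w` — weight of the two target terms relative to the imaging–genetic
  term; default 1 (equal weighting of the three pairwise associations, as
  in the symmetric three-way family). The published account of this
  weight refers to an external formula that is not reproduced; equal
  weighting is this package's own choice and is configurable.
* `tol = 1e-6` on the sup-norm change of the loadings, `max_iter = 100`;
  typical convergence is well under 30 sweeps.

## Penalty tuning

Penalties are tuned per training set by internal five-fold
cross-validation of the mean of the three held-out Pearson correlations
$\tfrac13[\mathrm{corr}(X_i u_{-i}, Y_i v_{-i}) +
\mathrm{corr}(X_i u_{-i}, Z_i) + \mathrm{corr}(Y_i v_{-i}, Z_i)]$,
averaged over folds. A zero-variance projection (all loadings shrunk away)
contributes 0 to its term, so over-shrunk pairs are valid but unattractive;
a grid on which *every* pair is degenerate is an error.

The default grid is data-adaptive: 10 log-spaced values per penalty
spanning $[0.05\,g^\ast,\ g^\ast]$, where $g^\ast$ is the sup-norm of the
initial block gradient (at $g^\ast$ the first update is fully shrunk to
zero, so the grid brackets every attainable sparsity level; below
$0.05\,g^\ast$ solutions are fully dense and the grid would waste
points). The singular vector used to evaluate $g^\ast$ is oriented so the
bilinear and target terms add rather than cancel — with the arbitrary SVD
sign the grid's upper end can otherwise collapse by an order of magnitude.

Three selection rules are available:

* `"max_mean_1se"` (default): among all pairs within one standard error
  (across inner folds) of the best mean score, take the sparsest (largest
  $\lambda_u + \lambda_v$). The plain CV maximum is nearly flat once the
  signal features are included, so it systematically keeps noise features;
  the one-standard-error guard is the same remedy `glmnet` users know.
* `"max_mean"`: the plain maximizer, ties broken toward sparsity.
* `"mean_best"`: average of the per-fold best pairs — a literal reading of
  "average ... as the hyperparameters" that some descriptions of fold-wise
  tuning suggest; provided for comparison.

## The nested evaluation pipeline

`oscca_nested_cv()` wraps everything in nested five-fold cross-validation.
Per outer fold: standardization statistics are computed on the training
rows only and re-applied (unchanged) to the held-out rows; penalties are
tuned by inner five-fold CV inside the training rows; the model is fitted
and the non-zero loadings become the fold's selection; random forests (500
regression trees; other forest settings at library defaults) are trained
on the selected imaging, genetic, and combined feature sets plus a
constant mean-of-target baseline; the held-out fold is scored by Pearson r
(with its two-sided p) and RMSE in target units. Metrics are averaged
across folds — including the p-values, which therefore form a descriptive
summary, not a combined test; pooled-prediction correlations are reported
separately and never substituted. Features selected in *every* outer fold
are the consensus set. Mean imputation of missing genotypes and all
standardization use training-fold statistics only, so no information flows
from a test row into fitting — the suite asserts this by mutating held-out
rows and checking bit-identical loadings.

The LASSO comparison selector regresses the target on each block
separately (`glmnet`, 5-fold CV over a 50-value path, CV-minimum rule;
an empty selection is legal and recorded). The mRMR comparison uses the
classic mutual-information-difference ranking with the feature count
matched per block to the main model's selection size; continuous features
are discretized into three levels at mean $\pm\,0.5$ sd, genotype counts
are used as-is. The published FS-score threshold of 0.2 is exposed as a
configuration value, not hard-coded, because the score scale depends on
the mutual-information estimator.

## Quality control and enrichment

Variant QC reimplements the standard panel arithmetic on matrices: minor
allele frequency $\ge$ 0.01, call rate $\ge$ 0.95, exact conditional
Hardy–Weinberg test $p \ge 10^{-6}$ (Wigginton-style enumeration of the
heterozygote distribution given allele counts, the convention of the
standard genotyping toolchain; no mid-p), with genotype-quality masking at
GQ < 20 upstream. Monomorphic sites get HWE $p = 1$ so they fall to the
MAF filter, not the HWE filter. Missing genotypes are mean-imputed *after*
QC — the simplest choice that approximately preserves the 0/1/2 scale.

Enrichment is one-sided hypergeometric over-representation of the genes
mapped from the selected variants (slash-separated multi-gene annotations
map to all their genes), Benjamini–Hochberg-adjusted across the tested
sets only. The reference universe is caller-supplied; no gene-set database
is bundled.

## What the synthetic generator emulates — and what it does not

`sim_dataset()` plants a genotype-driven latent factor: $L$ is the
standardized equal-weight allele score of `s_y` causal variants, the
`s_x` causal imaging features load on $L$ with independent Gaussian noise,
and the target is $\mu_z + \delta_z L + \varepsilon$. Because $Y$ causes
$L$ which causes both $X$ and $Z$, all three pairwise associations are
simultaneously positive — the regime the three-term model assumes.

Default shape: 146 subjects, 90 imaging features, 72 variants, supports of
14 and 24 — the dimensions of the Parkinson's AAO cohort this package is
designed around. Frequencies are drawn from (0.2, 0.5), a curated panel of
common disease-associated variants. The default noise levels are the
"strong signal" validation regime: imaging SNR 2 (`gamma_x = 1`,
`sd_x = 0.5`) and `delta_z = 9`, `sd_z = 4` years, which makes the total
target sd about 9.8 years (similar to a realistic AAO spread) with the
latent carrying roughly 83% of target variance. `delta_z = 3` serves as
the weak regime and `delta_z = 0` as the null.

Not emulated: linkage disequilibrium (variants are independent draws),
population structure, spatially correlated imaging noise, and any
missingness mechanism beyond uniform dropout. Passing the recovery tests
therefore demonstrates correctness of the machinery under clean sparse
cross-modal structure — not performance on real cohort data, where LD and
confounding can make both selection and prediction substantially harder.

### A structural limit worth knowing

With `s_y = 24` causal variants driving a single latent, the squared
per-variant correlations with $L$ sum to at most 1, so each variant's
correlation is capped at $1/\sqrt{24} \approx 0.20$ and its association
z-score at $\approx 0.20\sqrt{146} \approx 2.5$ — overlapping the extreme
order statistics of the 48 null variants. Even thresholding the loading at
the truth-optimal level (an oracle unavailable in practice), the median F1
of the genetic support is about 0.78 at this shape; the honest CV-tuned
pipeline reaches roughly 0.6–0.7, while the imaging support (per-feature
correlation ≈ 0.9, no aggregation cap) is recovered essentially perfectly.
This is an information limit of the study dimensions, not a solver
deficiency; genetic-support recovery improves directly with larger $n$ or
smaller causal sets.

## Numerical choices and degenerate inputs

* Standardization uses the sample (n−1) standard deviation; zero-variance
  columns are centered, divided by 1 and flagged.
* Correlations of zero-variance projections are returned as `NA` by the
  low-level helpers and counted as 0 only inside the tuning score.
* Ties in the tuning grid break toward the sparser pair; ties in mRMR
  break toward the lower feature index; the SVD initialization fixes its
  arbitrary sign by making the largest-magnitude entry positive.
* All randomness (folds, forests, the generator, LASSO fold assignment)
  derives from explicit integer seeds; re-running any stage with the same
  configuration is bit-identical.
* Problem sizes used in the validation suite: solver-vs-reference checks
  use up to 4×4 loadings on up to 20 subjects; pipeline-level recovery and
  signal-response checks run the full 146×90×72 study shape across 20
  seeds per condition.

## Known limitations

Only the first canonical component pair is estimated. The target block
must be a single column; the scalar weight would become a loading vector
for a multi-column objective, which is out of scope. The fold-averaged
p-value is descriptive. The mRMR estimator is plug-in and its FS scores
are scale-dependent. No VCF parsing or genotyping-tool invocation is
included: QC operates on the recoded allele-count matrix.
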