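---
title: "Pathway-level multi-omics integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level multi-omics integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathblend)
```

# Overview

`pathblend` models a clinical outcome from several omics views measured on
the same individuals by first collapsing each sample-by-molecule matrix
into a sample-by-pathway activity matrix, then fitting a supervised model
on pathway scores. This vignette is the package's own account of the
science: the transforms and the model, the assumptions behind them, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical conventions that make runs
reproducible.

# Preprocessing

Raw abundances are assumed strictly positive and roughly log-normal;
`log2_transform()` puts them on a log2 scale so that additive effects are
fold changes. Standardization (`fit_standardizer()` /
`apply_standardizer()`) sets each feature to mean 0, standard deviation 1
using the sample (n − 1) standard deviation — the usual convention, and
the one under which the hand-checkable example {2, 4, 6} maps to
{−1, 0, 1}. The fit/apply split matters: in every cross-validation fold,
scaling parameters are learned on the training portion and applied
unchanged to the held-out portion. The same discipline applies to the
ssPA transforms; these leakage rules are asserted by tests that corrupt a
held-out set and verify training outputs do not move.

Missing values are imputed by iterative truncated-SVD completion
(`svd_impute()`): initialise missing cells at column means, then
repeatedly replace them with their rank-r reconstruction until the
imputed entries change by less than `tol` in Frobenius norm. Defaults —
rank `min(10, N − 1, M − 1)`, `tol = 1e-5`, `max_iter = 100` — are
exposed as arguments because no single rank suits all platforms; observed
entries are never altered, and imputation runs on the log2 scale before
(re)standardization so the low-rank structure is not distorted by scale.
`filter_low_variance()` optionally drops features below a variance
percentile (25 is a common choice for transcriptomics).

# Single-sample pathway analysis

For each pathway the member molecules observed in the data (its
*coverage*) define a submatrix `Z_i`. Two scoring methods are available:

- **SVD (PLAGE).** The score is the projection of the column-centred
  `Z_i` onto its top right-singular direction — the first principal
  component score. It is linear, fast, and exposes per-molecule loadings
  (`molecule_loadings()`, with bootstrap stability via
  `bootstrap_loadings()`, default 200 replicates).
- **kPCA.** Kernel PCA on `Z_i` with an RBF kernel; the score is the
  first component scaled as eigenvector times the square root of its
  eigenvalue (the principal-component score convention). The kernel
  width defaults to `gamma = 1/L_i`, the scale-free heuristic in the
  submatrix dimension; it is a tuning argument. kPCA can pick up
  non-linear coordination but has no molecule loadings.

Coverage filtering defaults to 2 observed members per pathway — a
deliberately liberal floor below which a "pathway" score is just a single
molecule. Simulation target pathways require 3, so a spiked signal is
genuinely distributed; both thresholds are arguments, not constants.

Numerical conventions: the first principal component's sign is arbitrary,
so directions are oriented to make the sum of loadings positive (ties:
largest-magnitude loading positive). For coherent pathways a higher
score then means higher average member abundance, and refits on identical
data give identical output. Column centring inside each `Z_i` uses
training means even though standardized training data is already centred
— this makes fit/transform exact on the training set and correct
out-of-sample. A constant (zero-variance) submatrix yields all-zero
scores with a warning rather than an error, keeping matrix shapes stable
under degenerate simulated inputs.

# Supervised models

## Multi-View: multi-block PLS

`fit_mbpls()` implements NIPALS MB-PLS with superscore deflation: block
weights are unit norm within each block, superweights unit norm across
blocks, and every block **and** the outcome are deflated by the
superscore. This is the variant that renders superscores orthogonal
across latent variables — an invariant the test suite asserts — and it
makes the model algebraically a single PLS on the concatenated matrix
whose global weight per latent variable stacks `a_k * w_k` (itself unit
norm), which is how prediction (`beta = W (P'W)^{-1} C'`) is computed.
With one block the model reduces *exactly* to single-block PLS, checked
against an independently coded NIPALS oracle.

Choices worth recording:

- `SSY_r`, the outcome sum of squares explained by latent variable `r`,
  is computed as the drop in the residual `Y` sum of squares across the
  deflation step — the quantity the VIP definition needs but which is
  otherwise underdefined.
- VIP uses the deflated-matrix weights `W`, not the original-variable
  weights `W*`; under this convention the identities `mean(VIP^2) = 1`
  and `SS(MB-VIP)/(f k) = 1` hold to machine precision, and both are
  asserted on every fitted model in the tests. For MB-VIP the per-block
  unit-norm weight convention is the unique one under which the `f k`
  identity holds.
- Binary outcomes are encoded 0/1 and centred (PLS-DA); class calls
  threshold the continuous score at 0.5, and AUROC is always computed on
  the continuous score.
- Latent-variable signs are fixed by making the largest-magnitude
  superweight entry positive.
- Convergence: relative superscore change below `1e-10`, at most 500
  iterations per latent variable (with a univariate outcome NIPALS
  converges in two); non-convergence is an error naming the latent
  variable. Requesting more latent variables than the rank of the
  concatenated blocks is an error.

The number of latent variables is *not* chosen inside `fit_mbpls()`;
`nested_lv_selection()` does it by stratified inner cross-validation,
fitting once per fold at the largest candidate and evaluating smaller
counts by truncated prediction, then applying the one-standard-error
rule (smallest count within one SE of the best mean AUC). On
semi-synthetic data with a single spiked pathway this selects one latent
variable, as it should.

## Single-View: one predictor on concatenated scores

`fit_singleview()` concatenates the blocks *before* scoring, so a
pathway's submatrix may mix metabolites and proteins; multi-omics
coverage is therefore at least the per-omics maximum. Blocks are
standardized before joining and not re-weighted by size — the pathway
transformation itself is the cross-omics harmonizer. The predictor is
pluggable via `predictor_spec()`: PLS (importance = VIP), random forest
(importance = normalized Gini impurity decrease; defaults 200 trees,
node size 4 follow commonly tuned values for pathway-score inputs),
logistic regression (importance = |coefficient|), or a custom
fit/predict pair. Importance ties are broken by pathway id so rankings
are deterministic. `rfe_select()` adds recursive feature elimination
with cross-validation, dropping the weakest 10% of remaining features
per step (a standard rate, exposed as an argument) and preferring fewer
features at equal CV score.

# Inference

`permutation_pvalues()` permutes the outcome labels, refits an arbitrary
per-feature statistic (MB-VIP via the `permute_mb_vip()` wrapper), and
counts `p = #(permuted >= observed)/n_perm`. Deliberately there is no
`+1/(n+1)` correction: p-values live exactly on the `1/n_perm` grid, a
statistic above every permuted value reports p = 0, and such entries
should be read as "< 1/n_perm". 10,000 permutations give a resolution of
0.0001. Permutations are full label shuffles without excluding the
identity — at that depth collisions are immaterial. Under a true null
the empirical p-values are (weakly) conservative, which the suite checks
over 200 replicate datasets. Benjamini–Hochberg FDR is applied across
features; `bonferroni()` is used where a family-wise bound is wanted
(metadata screening, univariate experiments).

`bootstrap_block_importance()` (default 100 replicates) resamples
samples, refits, aligns replicate latent variables to the full-data model
by maximal absolute superscore correlation, and reports mean and SEM of
the squared superweights. `correlate_superscores()` screens latent
variables against clinical metadata by Spearman correlation with
Bonferroni correction, flagging |rho| >= 0.3 and adjusted p <= 0.05 by
default.

# The semi-synthetic benchmark

## What the generator emulates

`generate_base()` draws each omics block from a Gaussian factor model:
every pathway owns a latent factor and its member features load on it so
that same-pathway features correlate at `rho`; an optional global factor
adds a baseline correlation across all features and blocks
(`cross_block_rho`, default 0 — the benchmark design deliberately carries
no built-in between-omics correlation). Features are log2-scale by
construction and each block is standardized. A fraction of pathways
(default 0.1) borrow a member from a neighbour so pathway sets overlap,
as they heavily do in curated databases. The outcome is balanced binary
and independent of the data.

Defaults are the package's study conditions: N = 200 samples, 100
pathways of 4–8 molecules over 2 blocks, `rho = 0.5`. Calibration
experiments that only need a null run at N = 100 with 50 pathways to keep
the suite fast; these sizes are stated where used.

What it does **not** emulate: heavy-tailed and skewed abundance
distributions, missingness, batch effects, block-specific noise levels,
the long-tailed pathway-size distribution of real databases, and
hub-molecule structure. Passing tests therefore demonstrate correctness
and the direction of trends, not effect-size magnitudes on real data.

## Spike-in realisations

`make_realisation()` shuffles the outcome labels — erasing any real
outcome association while preserving the molecular covariance — and adds
a constant `alpha` (a log2 fold change) to the covered members of one
target pathway in the new case group only, across every block containing
them. Locality is exact and tested: precisely |case| x coverage entries
change, each by exactly `alpha`. Targets must have coverage >= 3.

## Experiments

- `univariate_experiment()` compares detection of the spiked pathway by
  a Mann–Whitney U test on its ssPA score (Bonferroni-corrected over all
  scored pathways) against molecule-level testing (Mann–Whitney U per
  member, Bonferroni over **all molecules measured in the data** — the
  multiplicity a molecular screen carries — gated conditional Fisher
  combination across members: combine all member p-values when at least
  half are significant, else report 1). Both corrections are
  screening-wide so the comparison is like for like; correcting the
  molecular route only over the handful of target members would make it
  artificially easy. Target and label shuffle are shared across effect
  sizes within a realisation index, so power curves are paired. At
  `alpha = 0` both routes reject at most at the nominal rate; power rises
  with `alpha`, and at moderate effect the pathway route dominates — the
  aggregation gain the package exists to exploit.
- `cv_auroc()` runs the full pipeline (per-fold standardization, ssPA,
  model) under 5-times-repeated stratified 5-fold cross-validation and
  summarises fold AUROCs with a normal-approximation 95% CI.
- `evaluate_detection()` scores one realisation's adjusted p-values:
  confusion counts at 0.05 and a ranking AUC over non-targets with the
  midrank tie rule (permutation p-values tie heavily on the `1/n_perm`
  grid). Per-realisation AUCs are averaged across realisations rather
  than pooled into one ROC.
- `downsample_experiment()` subsamples to a 1:1 class ratio at each
  requested size and reruns `cv_auroc()`.

Realisation seeds are independent children of one master seed, so every
experiment is reproducible and realisations are mutually independent.

# Known limitations

- MB-PLS handles a single outcome column; multivariate outcomes are out
  of scope.
- No sparse or regularized variants; importance is dense MB-VIP.
- Samples missing an entire omics view are dropped at alignment rather
  than modelled.
- kPCA pathway scores have no molecule-level loadings; use the SVD
  method when per-molecule attribution matters.
- The generator's Gaussian blocks make standardization nearly the
  identity, so spike effects are simultaneously in standard-deviation
  and log2 units; on real data those scales differ per molecule.
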