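---
title: "Joint deep semi-NMF: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint deep semi-NMF: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jdsnmf)
```

## The model

Given $I$ data matrices $X_1 \in \mathbb{R}^{C \times M_1}, \dots,
X_I \in \mathbb{R}^{C \times M_I}$ that share their row entities — the
*matched axis*, which is the samples when several omics layers were
measured on one cohort (sample-matched), or the features (genes) when the
same modality was measured in several cohorts (feature-matched, after the
loader transposes) — the joint deep semi-NMF decomposition solves

$$
\min \; \sum_{i=1}^{I}
\bigl\lVert X_i - U\, g\!\left(Z_i^1\, g\!\left(Z_i^2 \cdots
g\!\left(Z_i^N H_i^N\right)\right)\right) \bigr\rVert_F^2
\;+\; \lambda \sum_{S} \lVert S \rVert_F^2 ,
$$

where $U \in \mathbb{R}^{C \times K_0}$ is a single latent matrix shared by
all blocks along the matched axis, $Z_i^n \in \mathbb{R}^{K_{n-1} \times
K_n}$ are per-block junction matrices, $H_i^N \in \mathbb{R}^{K_N \times
M_i}$ is each block's deepest latent, and $g$ is an elementwise activation
(sigmoid by default, ReLU or identity alternatively). The intermediate
layer latents are *derived*, $H_i^{n-1} = g(Z_i^n H_i^n)$, so they are
non-negative by construction — in $(0,1)$ under the sigmoid — while $U$,
the $Z_i^n$ and $H_i^N$ carry unconstrained signs. This is the "semi" part:
only the hierarchy of derived representations is non-negative, so the data
themselves may be mixed-sign (log-ratios, centered expression, etc.).

The regularizer sums *squared* Frobenius norms of all free factors. The
penalty could also be read as a sum of unsquared norms; we use the squared
form because it is the standard L2/weight-decay penalty, is smooth at zero,
and matches the description of the tuning constant as an "L2 norm
parameter". Derived layers are not penalized; their magnitude is already
bounded through $g$.

Two special cases orient the model family: with one block, one layer and
the identity activation the problem is exactly semi-NMF, whose optimal
objective at rank $K$ is the truncated-SVD (Eckart–Young) residual — we use
that as a correctness oracle. With non-negative inputs and non-negativity
imposed on both factors one recovers classical NMF, which the package
provides independently (`nmf_multiplicative()`, Lee–Seung updates) as the
linear baseline.

### Configuration

`model_config(dims, ...)` collects the hyperparameters that matter:

* `dims` — layer widths $K_0 \ge K_1 \ge \dots \ge K_N$, with $K_0 <
  \min(C, \min_i M_i)$. The canonical deep configuration uses strictly
  decreasing widths (e.g. `c(60, 59, 44)` for a three-layer fit on omics
  cohorts); equal consecutive widths are allowed, and `c(K, K)` with the
  identity activation is exactly rank-$K$ semi-NMF. The first-layer width
  $K_0$ is also the number of modules constructed later.
* `activation` — `"sigmoid"` (default; bounded, gives (0,1) layer latents),
  `"relu"`, or `"identity"` (linear; used for oracle comparisons).
* `l2_lambda` — the L2 penalty $\lambda \ge 0$ (unitless; 0.01 is a typical
  operating point for standardized omics matrices).
* `learning_rate`, `max_epochs`, `patience`, `tol`, `lr_decay`,
  `max_anneals` — optimizer settings described next.

## Optimization

The free parameters are optimized jointly by full-batch Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$) on analytic gradients obtained by
backpropagating through the layer recursion. Training monitors the total
objective: when the best value fails to improve by a relative `tol`
(default $10^{-5}$) for `patience` consecutive epochs, the optimizer
*anneals* — it restores the best snapshot, multiplies the learning rate by
`lr_decay` (default 0.5) and resets the Adam moments — up to `max_anneals`
times, after which it stops early. The returned model is always the
best-objective snapshot, and seeded runs reproduce bit-for-bit. A
non-finite objective aborts with the epoch and learning rate, which in
practice indicates a learning rate far too large for the data scale.

Plateau annealing is worth its small complexity here: the composition of a
bounded activation with bilinear factors produces long, narrow valleys in
which a fixed Adam step either crawls or oscillates; halving the step at
plateaus finishes the descent that a plain early stop would abandon.

### Initialization

`svd_initialize()` is deterministic. The blocks are concatenated
column-wise; a truncated SVD at rank $K_0$ gives $U = u\,\mathrm{diag}(d)$
and each block's first-layer latent as its slice of $v^\top$; deeper
factors come from recursively applying a truncated SVD at each layer's
width. Singular-vector signs are fixed (largest-magnitude entry of each
left vector positive) so repeated runs agree exactly. Deeper latents are
factored as-is, without mapping them through an inverse activation: the
right singular factors are already small, so the subsequent sigmoid
operates near its linear range.

A refinement, enabled with `preact_spread` (recommended value 2), rescales
each layer's factors so its pre-activation has that standard deviation —
spreading a sigmoid across most of its responsive range instead of its
near-linear center — and then re-solves $U$ by least squares against the
first layer *as actually derived through the activation*. This starts the
optimizer far closer to the data in reconstruction terms and is the warm
start we use for generative-recovery analyses, where it reliably reaches
reconstruction error at the noise floor. It is not the default because the
classical start retains variance-aligned structure in $U$ — essentially
principal-component directions — which is demonstrably better for the
downstream classification use of $U$ rows: on the simulation benchmark
below, fits from the refined start reconstruct slightly better yet
classify worse. The two starts are two documented operating points, chosen
per analysis goal.

## Modules

Module $k$ (one per first-layer dimension, $K_0$ in total) is defined by
z-score thresholds on the first-layer latents:

* **samples** (per block): entries of row $k$ of that block's $H^0$
  exceeding $\mu + 1.6449\,\sigma$ — the upper 5% tail of a normal fit;
* **features**: entries of column $k$ of $U$ beyond $\mu \pm
  2.5758\,\sigma$ — the two-sided 1% tails, split into positive and
  negative feature sets.

$\mu$ and $\sigma$ (population form, `ddof = 0`) are computed per latent
dimension, not pooled over the whole matrix: each module's score
distribution has its own location and spread, and pooling would let a few
high-variance modules absorb every selection. A `global = TRUE` flag
provides the pooled alternative for comparison. Sample thresholds are
computed per block, since each block's sample latent has its own scale.
Entities may belong to several modules; a zero-spread dimension selects
nothing and warns. On i.i.d. Gaussian latents the expected membership
fractions are 5% (samples) and 1% (features in total) — the calibration the
test suite checks. Note a small-sample subtlety of the rule: a single
outlier pair among $n$ values inflates $\sigma$ itself, so for $n \lesssim
20$ even an extreme value may legitimately fail the $2.5758\,\sigma$
cutoff.

## The simulation benchmark

`simulation_design()` encodes the sample-matched benchmark conditions:
per view, $X \in \mathbb{R}^{S \times F}$ with i.i.d. $N(0,1)$ entries;
1000 features of which 20 are informative with coefficients $\pm 10$
(random sign, random positions); class probability
$y_s = \mathrm{expit}(\beta_0 + \sum_f \beta_f x_{sf} + \epsilon_s)$ with
$\epsilon \sim N(0, 1.6)$ — we read "N(0, 1.6)" as *variance* 1.6 and
expose the parameter as `noise_var` to remove the ambiguity; three views;
750/50/100 train/validation/test samples. The intercept $\beta_0$ defaults
to 0 and hard labels threshold the probability at 0.5, with Bernoulli
sampling available as an option. Label consistency across views is
enforced by rejection sampling — candidate samples are drawn under every
view's model and kept only when all hard labels agree (acceptance is about
$2^{-(V-1)}$ under these coefficient scales; a rate below $10^{-3}$
aborts with advice to increase the coefficient magnitude).

The generator emulates the benchmark's distributional shape — sparse
strong signal among many irrelevant Gaussian features, label noise, shared
labels across views. It does not emulate real multi-omics structure:
correlated features, block covariance, heavy tails, batch effects, or
feature-matched cohort heterogeneity. Passing benchmark tests therefore
demonstrates correct behavior under the stated generative conditions, not
performance on real cohorts.

`run_benchmark()` follows the evaluation protocol: per replicate, fit each
feature-extraction method on all samples (unsupervised), select
hyperparameters by validation AUC of a fixed linear SVM, report test AUC
of the selected features; test labels never inform selection. The NMF
baseline receives the column-concatenated views min-shifted into the
non-negative orthant (`shift_nonneg()`), since multiplicative NMF requires
non-negative input and the Gaussian views are mixed-sign. Classifiers are
pluggable with fixed settings: linear SVM (`e1071`, internally
standardized — latent dimensions can carry arbitrary relative scales),
random forest (500 trees by default; enough for stable rankings at these
problem sizes), and a single-hidden-layer network with weight decay
(`nnet`). AUC comes from `pROC`. Method comparisons over matched
fold-by-classifier AUC vectors use the two-sided paired Wilcoxon
signed-rank test (normal approximation, so tied AUCs are tolerated).

At desk scale we run the benchmark at $S = 300$ (250/20/30), $F = 200$ per
view, 20 informative features, over 5 replicates in the test suite and 20
replicates (the protocol's own repeat count) in the reproduction script;
these sizes keep the full analysis in the low minutes on one core while
preserving the qualitative ordering — joint non-linear features beat NMF
features by 3–5 AUC points on average.

## Interpretation

* `local_surrogate_importance()` explains any probability-scoring
  classifier over module features by local linear surrogates: Gaussian
  perturbations around each explained instance (scaled by each feature's
  spread), exponential kernel weights on standardized distance (width
  $0.75\sqrt{d}$ by default), and a weighted ridge fit (penalty $10^{-3}$);
  a module's importance is the summed absolute surrogate weight over
  instances and classifiers. On globally linear classifiers the recovered
  ranking equals the $|$coefficient$|$ ranking — the faithfulness property
  the tests assert. Perturbation count, kernel width and ridge penalty are
  all configurable; results are seeded.
* `rf_module_importance()` reports mean-decrease-in-impurity importance
  normalized to sum to one.
* `age_regression()` fits, per module, ordinary least squares of the
  module's sample-latent value on age, sex, diagnosis, and the leading
  principal components of the sample latent that are *unrelated to age*.
  "Unrelated" is operationalized as a Pearson correlation test p-value
  $\ge 0.05$ (configurable), screened over the first 10 PCs (configurable):
  the PC adjustment removes broad latent structure while leaving the age
  axis estimable, and capping the screen keeps the design well-conditioned
  when there are many modules. Constant covariates are dropped with a
  warning. The sign of the age coefficient $\gamma_j$ carries the
  direction of the association. Raw p-values are reported, as in the
  analyses this supports; apply `p.adjust` downstream if desired.
* `overlap_fisher()` is the general replacement for external enrichment
  services: a two-sided Fisher exact test of a module's gene set against
  any user-supplied reference set (e.g. read with `read_gmt()`) within a
  stated universe.
* `importance_vs_pathway_regression()` correlates per-module importance
  with per-module pathway-overlap counts (Pearson r, two-sided test, OLS
  slope).

## Numerical choices and degenerate inputs

* Multiplicative NMF guards denominators with $10^{-10}$; zero rows decay
  to zero instead of producing NaNs. Random init uses $|N(0,1)|$ entries;
  SVD init clips the truncated SVD at zero (NNDSVD-style) with the same
  epsilon floor.
* `jdsnmf_objective()` decomposes exactly into per-block fit terms plus
  the regularizer; tests assert the identity to $10^{-9}$ relative.
* All-constant blocks are rejected at initialization (the SVD is
  degenerate); zero-variance blocks warn at construction but are kept —
  no silent filtering.
* Model directories round-trip through plain TSV plus a JSON sidecar;
  loading validates every factor's shape against the stored configuration
  and fails with an integrity error on any mismatch.
* In sample-matched mode the per-sample features are the rows of $U$ — the
  only per-sample object shared across blocks — regardless of the chosen
  layer; in feature-matched mode the chosen layer's $H^{\ell}$ (transposed)
  supplies per-sample features and the layer is a real hyperparameter.
  Both are exposed through `extract_features()`.

## Problem sizes used in the shipped analyses

The test suite and `scripts/acceptance.R` run everything from scratch:
oracle comparisons on 50×40 matrices (20 runs), nested-loop composition
checks on 100 small random models, generative recovery at $C = 40$,
$M = 30$, $K = (5,4)$ over 20 seeds, the reduced benchmark above, 10,000-
entity membership calibrations, a planted-coefficient age regression at
$n = 200$ with 1000 null modules, and exhaustive-plus-randomized
hypergeometric verification of the Fisher test. These sizes are the
package's chosen desk-scale study conditions; all conclusions stated in
this vignette are the ones those computations actually produce.

## Known limitations

* The joint objective weighs blocks uniformly; blocks with many more
  columns or larger scales dominate the shared latent unless the user
  balances them beforehand.
* The factorization is non-convex: different warm starts reach different
  (near-)optima, which is why the two documented initializations exist and
  why seeds are part of the configuration.
* No missing-data support: matrices must be complete (impute upstream).
* The NMF baseline implements only the Frobenius objective with
  multiplicative updates — no KL divergence, no sparsity penalties.
* Batch correction, probe-to-gene mapping and other cohort preprocessing
  are out of scope; inputs are assumed analysis-ready.
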