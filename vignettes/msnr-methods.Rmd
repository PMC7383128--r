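---
title: "Multi-scale network regression: model, estimation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale network regression: model, estimation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnr)
```

## The model

For each of $n$ subjects we observe a symmetric $p \times p$ weighted
adjacency matrix $A^i$ (typically Fisher-z transformed correlations between
regional brain activity time series) and a vector of $q$ covariates $X_i$
(e.g. age, sex, in-scanner motion). The $p$ nodes carry a known partition
into $K$ communities with indicator matrix $W \in \{0,1\}^{p \times K}$.
The model is

$$A^i \;=\; \Theta \;+\; \sum_{f=1}^{q} X_{if}\, W \Gamma^f W^\top \;+\;
\varepsilon^i ,$$

with two structural assumptions that give the method its multi-scale
character:

* $\Theta$, the covariate-free mean connectivity shared by all subjects, is
  approximately **low rank** — nodes live near a $d$-dimensional latent
  space, as in random dot product graph models;
* each $\Gamma^f$, the $K \times K$ matrix of community-level covariate
  effects, is **sparse** — most community pairs have no association with
  the covariate, and the nonzero entries are directly interpretable
  ("one unit of standardized covariate $f$ changes mean connectivity
  between communities $k$ and $k'$ by $\Gamma^f_{kk'}$").

Rank and cardinality penalties are non-convex, so estimation uses their
standard convex surrogates — the nuclear norm $\|\Theta\|_*$ and the
elementwise $\ell_1$ norm $\|\Gamma^f\|_1$:

$$\min_{\Theta,\,\Gamma^1..\Gamma^q}\;
\sum_{i=1}^n \big\|A^i - \Theta - \textstyle\sum_f X_{if} W\Gamma^f W^\top
\big\|_F^2 \;+\; \lambda_1 \|\Theta\|_* \;+\; \lambda_2 \sum_f
\|\Gamma^f\|_1 .$$

## The diagonal convention

Self-connectivity is undefined for correlation networks, so every loaded
$A^i$ has its diagonal zeroed, predictions zero their diagonal, and the
community-mean formulas use off-diagonal entry counts
($|C_k|(|C_k|-1)$ within a community). Taken literally, "exclude the
diagonal from the loss" leaves $\Theta$'s diagonal appearing *only* in the
nuclear norm, and the $\Theta$ subproblem would no longer have a
closed-form solution. The package therefore solves, exactly,

$$G(\Theta, \Gamma) = \sum_i \big\|A^i - \Theta -
Z\!\big(\textstyle\sum_f X_{if} W\Gamma^f W^\top\big)\big\|_F^2
+ \lambda_1\|\Theta\|_* + \lambda_2 \textstyle\sum_f \|\Gamma^f\|_1,$$

where $Z(\cdot)$ zeroes the diagonal of the community term and $A^i$ has
zero diagonal. Relative to the prediction-based loss this adds an implicit
ridge $n \sum_j \Theta_{jj}^2$ that shrinks $\Theta$'s diagonal toward
zero. It is the unique convention under which **both** block updates below
are exact minimizers of one convex objective, so block coordinate descent
is provably monotone and reaches the global optimum. `msnr_objective()`
reports the prediction-based value (no diagonal ridge); the solver's
`objective_trajectory` reports $G$, which carries the monotonicity
guarantee. The two differ only through $\mathrm{diag}(\Theta)$, which the
ridge keeps near zero.

## Estimation: block coordinate descent with closed-form updates

Starting from $\Theta = 0$, $\Gamma = 0$ (convexity makes the optimum
independent of initialization), `msnr()` alternates:

* **Low-rank update** (`theta_update()`). With $\Gamma$ fixed, the
  subproblem is $n\|\Theta - \bar R\|_F^2 + \lambda_1\|\Theta\|_*$ with
  $\bar R$ the mean residual matrix. Its minimizer soft-thresholds the
  eigenvalues of $\bar R$ by $\lambda_1/(2n)$. For symmetric matrices the
  nuclear norm is the sum of absolute eigenvalues, so a symmetric
  eigendecomposition is exact and half the cost of an SVD.
* **Sparse update** (`gamma_update()`). With $\Theta$ fixed, the loss
  decouples over unordered community pairs $(k \le k')$: the residual
  entries of a block enter only through their mean $\bar y^i_{kk'}$ and
  count $m_{kk'}$, giving one weighted lasso
  $\min_\gamma m_{kk'} \sum_i (\bar y^i_{kk'} - x_i^\top\gamma)^2 +
  \lambda_2\|\gamma\|_1$ per block. (Between-community blocks appear twice
  in both the loss and the matrix $\ell_1$ norm; the factor 2 cancels.)
  Each lasso is solved by cyclic coordinate descent with exact scalar
  soft-threshold updates; blocks are processed in lexicographic order and
  covariates in input order. The implementation updates one covariate
  coordinate across *all* blocks at once — the blocks are independent
  problems, so this is identical to per-block cyclic descent, just
  vectorized. Within-community blocks of singleton communities have
  $m_{kk} = 0$ and their $\Gamma$ entries stay fixed at zero.

Convergence is declared when the relative objective change
$|G_t - G_{t-1}| / \max(1, G_{t-1})$ falls below `tol` (default `1e-6`,
scale-free and robust near zero); non-convergence within `max_iter`
(default 200) returns the model with `converged = FALSE` and a warning
rather than an error. The identifiability constraint
$\mathrm{Tr}(W^\top\Theta W) = 0$ of the population model is *not* imposed
(the convex program does not include it; covariate centering removes the
intercept confound in practice) and is instead reported as the diagnostic
`trace_WtThetaW`.

A consequence worth knowing: covariates are always column-standardized
before fitting, and with exactly centered $X$ the cross-term between
$\Theta$ and $\Gamma$ vanishes, so the two subproblems decouple and the
descent converges in essentially two iterations. The cross-validation hot
path exploits this analytically — $\Theta(\lambda_1)$ needs only a cached
eigendecomposition per fold, $\hat\Gamma(\lambda_2)$ is shared across all
$\lambda_1$ — and is verified against the generic solver path in the test
suite. The solver correctness itself is validated against an independent
proximal-gradient (FISTA) solver of the same convex objective on a battery
of small instances (relative objective agreement $10^{-5}$).

## Covariate standardization and leakage

Standardization statistics are always computed on the training portion and
reused for held-out subjects (`apply_standardization()`), at every level:
the outer train/validation split, each CV fold, and each permutation. A
fitted model stores its own center/scale so `predict()` and
`prediction_error()` accept raw-scale covariates. Constant covariate
columns are an error, never silently dropped.

## Tuning: cross-validation with grid refinement

`msnr_tune()` builds log-spaced grids of 10 points per dimension from
$10^{-3}\lambda_{\max}$ to $\lambda_{\max}$, where `lambda_max()` gives the
smallest penalties that fully shrink $\hat\Gamma$ (from the lasso zero
condition) and $\hat\Theta$ (from the spectral radius of the subject mean)
— the source study does not publish its grid bounds, so these bounds are the
package's own choice, anchored at analytically meaningful endpoints. After
five-fold CV, the grid is refined (default two rounds) to the interval
between the neighbors bracketing the argmin; the current argmin is kept in
the refined grid so refinement can never lose ground on the same folds. An
argmin on a grid edge extends the refined grid one octave beyond the edge
and emits a boundary warning. Exact ties in the error matrix break toward
the most regularized cell (largest $\lambda_1$, then largest $\lambda_2$)
for parsimony.

## Permutation test and its calibration

`permutation_test()` permutes whole rows of the covariate matrix across
all $n$ subjects (preserving the covariate covariance structure) with the
train/validation split held fixed, re-tunes the penalties by CV on the
training part for every permutation, refits, and records the validation
error; the p-value is the proportion of permuted-data errors at or below
the observed error (it can be exactly 0, logged as "< 1/N"), and a z-score
against the null distribution is reported.

Two design points were settled empirically during development:

* **Identical tuning effort.** An earlier default gave the observed data
  two grid-refinement rounds while permutations used only the coarse grid.
  That asymmetry is measurably anti-conservative: over 100 replicate null
  cohorts ($n = 60$, $p = 30$, $K = 3$, pure noise) the empirical type-I
  error at nominal 0.05 was 0.29. With identical pipelines for observed
  and permuted data (the current default, `refine_rounds = 0` for both)
  the same study gives 0.07, consistent with nominal up to Monte-Carlo
  error. The asymmetric mode remains available but is not recommended for
  inference.
* **Decoupled random streams.** The permutation draws use an RNG stream
  offset from the fold-assignment seed; reusing the identical integer seed
  would make the first permutation's prefix reproduce the fold draw.

The null distribution of the error statistic has atoms (many permuted
runs select the fully sparse $\hat\Gamma = 0$ and thus identical errors);
ties are counted in favor of larger p-values, which is the conservative
direction.

## Single-scale baselines

The two comparators deliberately mirror common practice:

* `edge_model()` fits one OLS regression per upper-triangle edge on the
  *raw* covariates plus intercept (the formula-interface convention), with
  Benjamini–Hochberg FDR correction of slope p-values at $q < 0.05$
  (Storey q-values with $\hat\pi_0 = \min(1, \overline{1\{p > 0.5\}}/0.5)$
  are available as an option). Out-of-sample prediction uses *all* fitted
  edge models, not only FDR-significant ones — optimistic by construction,
  and documented as such.
* `community_model()` regresses each within/between community mean
  (off-diagonal counts; singleton within-columns are dropped with a
  warning) on the same covariates, then broadcasts each predicted block
  mean to every edge of its block — the unique structure-preserving way to
  obtain the edge-level predictions that the shared error metric requires.

All three methods are scored by one routine,
`stack_prediction_error()` — the per-subject average squared Frobenius
distance between observed and predicted matrices — so method comparisons
cannot drift apart metrically.

## The synthetic-data generator

`simulate_msnr()` generates the world the estimator assumes:
$X$ i.i.d. standard normal then exactly column-standardized;
$\Theta^* = VV^\top$ with $V_{jk} \sim N(0, \sigma_\theta^2/\sqrt d)$
(low-rank PSD mean); $\Gamma^{*f}$ with unique entries nonzero with
probability $1 - s$ and values $\pm$`effect_size` with random sign; and
symmetric Gaussian edge noise. Defaults ($n = 200$, $p = 60$, $K = 6$,
$d = 3$, $q = 3$, sparsity $0.7$, effect $0.5$, noise SD $0.5$,
$\sigma_\theta = 1$) put the per-edge covariate signal on the order of the
edge noise while block averaging (blocks of ~100 edges) makes the
community-level signal strong — a "recoverable but not trivial" regime a
simulation study in this field would call realistic. These values are the
package's own stated world; they are fixed, documented here, and not
adjusted to test outcomes.

What the generator does *not* emulate: temporal autocorrelation of fMRI
noise, motion artifacts with spatial (distance-dependent) structure,
heavy-tailed edge distributions, or misspecified community assignments. A
green recovery test therefore establishes correctness of the estimator
under its own assumptions — not robustness to realistic violations of
them. `simulate_msnr_null()` (all $\Gamma^* = 0$) is the matching null
world for type-I calibration.

## Numerical choices

* Asymmetry up to $10^{-8}$ is symmetrized by averaging; beyond that it is
  an error. Nonzero diagonals are zeroed with a warning.
* Inner lasso coordinate descent stops at max coefficient change
  $10^{-8}$ (default), capped at 1000 sweeps; the outer loop at relative
  objective change $10^{-6}$, capped at 200 iterations.
* Penalty grids are strictly positive (log-spaced), so $\lambda = 0$ is
  reachable only by explicit user request.
* Serialized numerics use 17 significant digits (round-trip safe).
* Cross-community distance is the mean Euclidean distance over all
  cross-community node pairs (centroid-to-centroid is available); the
  effect-vs-distance correlation uses all unique $\Gamma$ entries
  including exact zeros by default (a `nonzero` option exists) — the
  source conventions for both are not published, so both choices are
  exposed.

## Known limitations

* The HDF5 container interchange format is not implemented (no HDF5 R
  bindings in the supported environment); adjacency stacks interchange as
  directories of per-subject TSV matrices.
* No inferential statements (standard errors, per-coefficient p-values)
  accompany the penalized $\hat\Gamma$; the permutation test assesses the
  model as a whole.
* Communities must be known a priori; estimating the partition, handling
  missing edges, and the non-convex rank/$\ell_0$ formulation are out of
  scope.
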