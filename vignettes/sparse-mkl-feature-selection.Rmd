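---
title: "Joint kernel feature selection and max-margin classification"
author: "mklfs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint kernel feature selection and max-margin classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mklfs)
```

## The model

`mklfs` classifies samples described by non-negative, histogram-like
feature tables — the motivating case is region-of-interest gray/white
matter volumes and striatal binding ratios derived from neuroimaging —
while *simultaneously* selecting the features and kernel types that drive
the decision. Instead of selecting features in the input space and then
training a nonlinear classifier (which optimizes two different criteria),
both happen in one convex objective.

The construction: every feature is min-max normalized to $[0,1]$, and for
each feature $m$ and each kernel type $t$ a base Gram matrix
$K_{m,t}$ is computed from that feature's scalar values alone. With $d$
features and $\kappa$ kernel types there are $b = d\kappa$ base kernels,
aggregated under a non-negative weight vector $\alpha$:

$$k_\alpha(x, z) \;=\; \sum_{m=1}^{d}\sum_{t=1}^{\kappa}
  \alpha_{m,t}\, k_t\!\left(x_m, z_m\right).$$

The classifier is a kernel SVM under $k_\alpha$, with the weights
penalized by an $\ell_1$ term:

$$\min_{f,\; \alpha \ge 0}\;
  \tfrac12 \lVert f \rVert_{\mathcal H_\alpha}^2
  + C \sum_j \max\bigl(0,\, 1 - y_j f(x_j)\bigr)
  + \lambda \lVert \alpha \rVert_1 .$$

Because each base kernel sees exactly one feature, a zero weight removes
that (feature, kernel type) pair from the model: the sparsity pattern of
$\alpha$ *is* the feature/kernel selection. Summing $\alpha$ over kernel
types gives per-feature relevance; averaging over features gives a
per-kernel-type importance readout (`kernel_mean_weights()`).

## Kernel set

Five scalar kernels are available (`kernel_spec()`), all standard choices
for non-negative histogram-like values:

| type       | form                              | captures              |
|------------|-----------------------------------|-----------------------|
| `linear`   | $a\,c$                            | global linear trends  |
| `rbf_euc`  | $\exp(-\sigma\,(a-c)^2)$          | smooth local similarity |
| `rbf_emd`  | $\exp(-\sigma\,\lvert a-c\rvert)$ | 1-D earth mover's distance |
| `rbf_chi2` | $\exp(-\sigma\,\tfrac{(a-c)^2}{a+c})$ | relative (chi-square) discrepancy |
| `hik`      | $\min(a, c)$                      | piecewise-linear, histogram overlap |

For scalar (single-bin) inputs the 1-D earth mover's distance reduces to
$\lvert a - c\rvert$, and the chi-square distance is defined as 0 at
$a = c = 0$ (its continuity limit). Every base kernel is positive
semidefinite on non-negative inputs, so any non-negative aggregation is
PSD as well.

**Why the rate parametrization.** The RBF kernels use
$k(D) = \exp(-\sigma D)$ with $\sigma = 0.5$ (the libsvm `gamma`
convention) rather than $\exp(-D/2\sigma^2)$. The choice is not cosmetic;
it decides which kernel types can be selected at all. On the SVM dual
manifold ($\sum_i \beta_i y_i = 0$) the histogram intersection kernel
contributes exactly $-\tfrac12 u^\top\!\lvert a-c\rvert\, u$ to the margin
term (where $u = \beta \odot y$), because its value part
$\min(a,c) = \tfrac{a+c}{2} - \tfrac{\lvert a-c\rvert}{2}$ loses the
$(a+c)$ component to the equality constraint. A first-order expansion of
the EMD-based RBF kernel contributes $-s\, u^\top\!\lvert a-c\rvert\, u$
where $s$ is the exponent slope at zero. Any slope $s > \tfrac12$ makes
the EMD kernel strictly dominate HIK for every feature, and the
$\ell_1$ penalty then never selects HIK — contradicting the well-documented
usefulness of HIK for exactly these features. At $\sigma = 0.5$ the rate
form gives $s = \tfrac12$: HIK and the EMD kernel tie at first order,
second order favors HIK, and the selection problem becomes a genuine
contest decided by the data.

## Optimization

The objective is convex and is minimized by alternating two subproblems
(`fit_alternating()`):

1. **SVM subproblem.** With $\alpha$ fixed, the problem is a standard
   hinge-loss SVM on the precomputed Gram matrix
   $K(\alpha) = \sum \alpha_m K_m$. It is solved in the dual by libsvm
   (`e1071::svm`): $K$ is factored through its symmetric
   eigendecomposition $K = V D V^\top$ and the rows of $V D^{1/2}$ are
   passed as explicit features under a linear kernel — the identical dual
   QP, solved by a battle-tested SMO. The eigenvalues double as a PSD
   guard: negative eigenvalue mass beyond $10^{-8}\,\mathrm{tr}(K)$ is an
   error, anything smaller is clipped.
2. **Weight subproblem.** With the dual solution fixed, the gradient of
   the optimal-value function in $\alpha$ has the reduced-gradient form
   $\partial J/\partial \alpha_m = -\tfrac12 u^\top K_m u + \lambda$
   (`grad_alpha()`). A projected gradient step
   $\alpha^+ = \max(\alpha - \eta\, g,\, 0)$ is taken with $\eta$ chosen
   by Armijo backtracking (`armijo_step()`); every trial point re-solves
   the SVM so the accepted objective is the true joint value and the
   recorded trace is monotone by construction.

Iteration stops when the relative objective change falls below
$10^{-4}$ or after 100 outer iterations. The combination of the
$\ell_1$ penalty and the projection produces *exact* zeros on inactive
blocks, so "selected" needs no threshold.

Numerical choices worth knowing:

* $\alpha$ starts uniform at $1/b$ — an unbiased, deterministic start.
* The Armijo search warm-starts each line search near twice the
  previously accepted step, so backtracking stays short once the step
  scale is known; the first iteration pays a longer backtracking run.
* The inner solver tolerance defaults to $10^{-4}$; gradient-accuracy
  tests tighten it to $10^{-10}$.
* Ties at $f(x) = 0$ predict the positive class, a fixed convention.
* An all-zero aggregated kernel (possible under extreme $\lambda$)
  degenerates to a majority-class constant decision.

Defaults $C = 10$, $\lambda = 1$, $\sigma = 0.5$ are the reference
values used in all shipped experiments; a cross-validated sensitivity
sweep over $\lambda$ (`lambda_sweep()`) is provided because the sparsity
trade-off is the one knob users will reasonably question. On
strong-signal data accuracy is flat across $\lambda \in [0.1, 10]$.

## Synthetic benchmarks

Two seed-controlled generators reproduce the benchmark study conditions
(50 dimensions, 100 samples per class, features normalized to $[0,1]$):

* **`gen_linear_subspace_data()`** — class $+1$ spans a random
  orthonormal basis $U_1$ (rank 25 by default), class $-1$ spans
  $U_2 = T U_1$ for a random rotation $T$. Subspace coefficients are
  i.i.d. $\mathrm{Uniform}(0,1)$, so each class occupies the convex cone
  generated by its basis. Two random rank-$d/2$ cones in general position
  admit a separating hyperplane, which makes this benchmark *genuinely*
  linearly separable — with zero-mean symmetric coefficients both classes
  would be centrally symmetric about the origin and no affine separator
  could beat chance. The rank default of half the ambient dimension keeps
  the two rotated subspaces distinct as sets.
* **`gen_sphere_shell_data()`** — class $+1$ uniform in the ball of
  radius $0.5$, class $-1$ uniform in the shell between radii $0.5$ and
  $1.0$ around the same center (direction uniform on the sphere, radius
  with density $\propto r^{d-1}$ on the appropriate interval). In 50
  dimensions both classes concentrate near their outer radii, giving two
  well-separated concentric shells that no linear rule can split.
* **`gen_informative_feature_data()`** — a controlled fixture: the first
  $k$ of $d$ features carry a class-mean shift of `effect` standard
  deviations, the rest are pure noise. Used for feature-recovery and
  permutation-calibration properties.

What these benchmarks do *not* emulate: correlated features, imbalanced
classes, heterogeneous feature families (volumes vs. binding ratios),
measurement noise on labels, or site effects — all present in real
cohorts. Passing them shows the optimizer selects the right kernel
*types* and separates clean geometry; it is not evidence about clinical
data.

Two behaviors observed on these benchmarks deserve an honest note.
First, because every feature of either generator is statistically
exchangeable with every other, the per-feature kernel competition has the
same winner in every feature, and the $\ell_1$ penalty drives the
solution toward a *single* kernel type per dataset (HIK on the cone
data; HIK plus the EMD kernel on the shells, where the two stay in
genuine competition). Coexistence of several kernel types with large
weights is typical for heterogeneous real features, not for exchangeable
synthetic ones. Second, the shell benchmark occasionally yields one or
two held-out errors (98.5–100% across seeds): per-coordinate marginals of
the two shells overlap slightly, and a per-feature kernel model has no
access to the joint radius. Both behaviors are properties of the method,
reported as measured.

## Evaluation machinery

* **`stratified_kfold_cv()`** — class-stratified folds; normalization
  bounds are re-estimated on each training split only, so no information
  leaks into the held-out fold. Headline ACC/SEN/SPE are pooled over the
  concatenated held-out predictions (one unambiguous number); fold-wise
  accuracies are kept alongside. AUC is the rank-based (Mann-Whitney)
  probability that a positive outscores a negative, ties counted half.
* **`permutation_test()`** — repeats the full CV under `pi` label
  permutations; $p = \#\{\text{null error} \le \text{observed}\}/\pi$
  (the plain "portion of runs" definition), with the add-one smoothed
  variant $(\#+1)/(\pi+1)$ reported alongside since the plain estimate
  can be exactly zero.
* **`bootstrap_eval()`** — resamples all $n$ subjects with replacement;
  the first 90% of the resampled order trains, the rest tests. The split
  is random because the resample order is; trials whose train or test
  part is single-class are skipped and counted.

## Problem sizes in the shipped tests

The test suite runs both benchmarks at their full size (200 samples, 50
features, 250 kernel blocks, 10-fold CV) and scales the property studies
to desk size: feature recovery uses 60 samples over 50 features across 10
seeds, and permutation calibration uses 20 permutations on 8-feature,
30-sample fixtures across 10 seeds with 3-fold CV. These sizes were
chosen so the full suite completes in minutes while keeping every
assertion at the full-dimensional structure of the method.

## Limitations

* Memory: all $b$ Gram blocks are materialized ($b n^2$ doubles;
  ~65 MB at $n = 180$, $b = 250$). Beyond a few thousand samples a
  compute-block-on-demand strategy would be needed; the stack container
  isolates that decision behind `get_gram()`/`aggregate_kernel()`.
* Each outer iteration re-solves an SVM per Armijo trial; training cost
  is dominated by the number of line-search evaluations.
* The per-feature kernel design cannot represent interactions that exist
  only jointly across features (the shell radius above is the canonical
  example); it trades that expressiveness for interpretable selection.
* Binary classification only; one-vs-rest extensions would need their
  own weight vectors per task.
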