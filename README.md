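# mklfs — sparse multiple-kernel feature selection with a max-margin classifier

`mklfs` is an R package for classifying samples described by
**non-negative, histogram-like feature tables** — the motivating
application is diagnostic modeling from neuroimaging-derived features
(region-of-interest gray/white-matter volumes and striatal binding
ratios) — while **selecting the informative features and kernel types in
the kernel space**, jointly with the classifier, rather than as a
separate preprocessing step.

## The method

One base kernel is built per (feature, kernel type) pair from five scalar
kernels suited to non-negative values: linear $a\,c$, histogram
intersection $\min(a,c)$, and RBF kernels $\exp(-\sigma D)$ over the
squared Euclidean, 1-D earth mover's ($|a-c|$) and chi-square
($\tfrac{(a-c)^2}{a+c}$) distances. With $d$ features and $\kappa$ kernel
types, the effective kernel is the weighted aggregate over all
$b = d\kappa$ blocks,

$$k_\alpha(x,z) = \sum_{m,t} \alpha_{m,t}\, k_t(x_m, z_m), \qquad
\alpha \ge 0,$$

and the model minimizes the $\ell_1$-regularized max-margin objective

$$\tfrac12\lVert f\rVert_{\mathcal H_\alpha}^2
 + C\sum_j \max(0,\, 1 - y_j f(x_j))
 + \lambda \lVert\alpha\rVert_1 .$$

Optimization alternates an exact SVM dual solve (libsvm on the
precomputed aggregated kernel) with projected-gradient steps on $\alpha$
under an Armijo line search. The $\ell_1$ penalty plus projection drives
inactive blocks to *exact* zeros, so the sparsity pattern of $\alpha$
doubles as the feature/kernel-selection readout. Defaults are the
reference values $C = 10$, $\lambda = 1$, $\sigma = 0.5$.

The package ships the full evaluation machinery (stratified k-fold CV
with ACC/SEN/SPE/AUC, permutation testing, bootstrap accuracy
distributions, $\lambda$ sweeps), two seed-controlled synthetic
benchmarks (linearly separable two-subspace data and nonlinearly
separable ball-versus-shell data, both 50-dimensional with 100 samples
per class), CSV/TSV feature-table I/O and a command-line interface.

## Worked example

Sixty samples over 20 non-negative features, of which only the first 4
carry class signal:

```r
library(mklfs)
dat <- gen_informative_feature_data(d = 20, n_informative = 4,
                                    n_per_class = 30, effect = 3, seed = 42)
fit <- mkl_fit(dat$X, dat$y)     # kernel_spec() + train_config() defaults
fit
#> Sparse multiple-kernel SVM
#>   samples: 60  features: 20  kernel types: 5  blocks: 100
#>   nonzero kernel weights: 4 of 100
#>   outer iterations: 24  converged: TRUE

ws <- kernel_mean_weights(fit)
ws
#> Mean kernel weight per kernel type:
#>   linear  rbf_euc  rbf_emd rbf_chi2      hik
#>   0.0000   0.0000   0.0000   0.0000   0.1949
#> Selected features: 4
round(ws$per_feature_weight[ws$per_feature_weight > 0], 3)
#>    f1    f2    f3    f4
#> 0.690 0.805 1.264 1.139

stratified_kfold_cv(dat$X, dat$y, k = 5, seed = 42)
#> 5-fold CV: ACC 100.0%  SEN 100.0%  SPE 100.0%  AUC 1.000
```

Of 100 candidate (feature, kernel) blocks the model keeps 4 — exactly the
four informative features, all under the histogram intersection kernel —
and classifies held-out samples perfectly. `mean_weight_per_kernel_type`
averages each kernel type's weights over all features (large values mark
kernel types the data favor); `per_feature_weight` sums each feature's
weights over kernel types (nonzero entries are the selected features).

The same pipeline is available from a shell; every run writes a JSON
manifest (config, seed, version, input checksums) next to its outputs:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mklfs", package = "mklfs"))')
Rscript "$CLI" synth --kind sphere --seed 1 -o data.csv
Rscript "$CLI" cv -i data.csv --k 10 --seed 1 -o cv.json
```

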