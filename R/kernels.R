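# Canonical kernel-type order; also the column order of the per-type
# mean-weight summaries.
MKLFS_KERNEL_TYPES <- c("linear", "rbf_euc", "rbf_emd", "rbf_chi2", "hik")

#' Kernel specification
#'
#' Defines the set of base kernel types and the RBF bandwidth used to build
#' one Gram matrix per (feature, kernel type) pair. The full default set has
#' five kernel types: the linear kernel, three RBF kernels differing in their
#' distance measure (squared Euclidean, 1-D earth mover's, chi-square), and
#' the histogram intersection kernel.
#'
#' @param kernel_types character vector, a subset of
#'   `c("linear", "rbf_euc", "rbf_emd", "rbf_chi2", "hik")` in the order the
#'   kernel blocks should appear.
#' @param sigma positive RBF rate: the RBF kernels are `exp(-sigma * D)`
#'   for distance `D` (the libsvm gamma convention; larger values give a
#'   narrower kernel).
#' @return an object of class `kernel_spec`.
#' @examples
#' kernel_spec()                      # all five kernel types, sigma = 0.5
#' kernel_spec("linear")              # plain linear kernel
#' @export
kernel_spec <- function(kernel_types = MKLFS_KERNEL_TYPES, sigma = 0.5) {
  kernel_types <- match.arg(kernel_types, MKLFS_KERNEL_TYPES,
                            several.ok = TRUE)
  if (anyDuplicated(kernel_types))
    stop("duplicated kernel types in spec", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a positive finite scalar", call. = FALSE)
  structure(list(kernel_types = kernel_types, sigma = sigma),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Kernel spec: kappa =", length(x$kernel_types),
      "(", paste(x$kernel_types, collapse = ", "), "), sigma =", x$sigma,
      "\n")
  invisible(x)
}

.check_nonneg <- function(..., .what = "input") {
  for (v in list(...)) {
    if (!is.numeric(v) || any(!is.finite(v)))
      stop(.what, " must be finite numeric", call. = FALSE)
    if (any(v < 0))
      stop(.what, " must be non-negative", call. = FALSE)
  }
  invisible(NULL)
}

#' Scalar distance and kernel primitives
#'
#' The per-feature kernels operate on scalar feature values, so all distances
#' reduce to scalar forms: the squared Euclidean distance `(a - c)^2`, the
#' chi-square distance `(a - c)^2 / (a + c)` (defined as 0 at `a = c = 0` by
#' the continuity limit), and the one-dimensional earth mover's distance,
#' whose cumulative-difference form collapses to `|a - c|` for single-bin
#' inputs. All are vectorized and require non-negative finite inputs.
#'
#' @param a,c non-negative numeric vectors (recycled).
#' @return numeric vector of distances.
#' @name scalar_distances
NULL

#' @rdname scalar_distances
#' @export
euclidean_sq_distance <- function(a, c) {
  if (!is.numeric(a) || !is.numeric(c) || any(!is.finite(a)) ||
      any(!is.finite(c)))
    stop("inputs must be finite numeric", call. = FALSE)
  (a - c)^2
}

#' @rdname scalar_distances
#' @export
chi2_distance <- function(a, c) {
  .check_nonneg(a, c)
  s <- a + c
  d <- (a - c)^2
  out <- numeric(length(d))
  nz <- s > 0
  out[nz] <- d[nz] / s[nz]
  out
}

#' @rdname scalar_distances
#' @export
emd_distance_1d <- function(a, c) {
  .check_nonneg(a, c)
  abs(a - c)
}

#' RBF kernel on a precomputed distance
#'
#' `exp(-sigma * D)`: equals 1 at zero distance and decays monotonically in
#' `D`. The rate parametrization (libsvm's gamma convention) is chosen so
#' that, at the default `sigma = 0.5`, the RBF kernel over the 1-D earth
#' mover's distance and the histogram intersection kernel agree to first
#' order on the SVM dual manifold; see the package vignette for why this
#' matters for kernel-type selection.
#'
#' @param D non-negative distances.
#' @param sigma positive rate.
#' @return values in (0, 1].
#' @export
rbf_kernel <- function(D, sigma = 0.5) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  .check_nonneg(D, .what = "distance")
  exp(-sigma * D)
}

#' Histogram intersection and linear scalar kernels
#'
#' `hik_kernel` returns `min(a, c)`, the histogram intersection similarity
#' for non-negative values; `linear_kernel` returns the product `a * c`.
#'
#' @param a,c numeric vectors (non-negative for `hik_kernel`).
#' @return numeric vector of kernel values.
#' @name scalar_kernels
NULL

#' @rdname scalar_kernels
#' @export
hik_kernel <- function(a, c) {
  .check_nonneg(a, c)
  pmin(a, c)
}

#' @rdname scalar_kernels
#' @export
linear_kernel <- function(a, c) {
  if (!is.numeric(a) || !is.numeric(c) || any(!is.finite(a)) ||
      any(!is.finite(c)))
    stop("inputs must be finite numeric", call. = FALSE)
  a * c
}

# One Gram block: kernel `type` applied elementwise to scalar feature values
# a (rows) vs c (cols).
.gram_block <- function(a, c, type, sigma) {
  switch(type,
    linear   = outer(a, c),
    hik      = outer(a, c, pmin),
    rbf_euc  = exp(-sigma * outer(a, c, function(x, z) (x - z)^2)),
    rbf_emd  = exp(-sigma * abs(outer(a, c, `-`))),
    rbf_chi2 = {
      num <- outer(a, c, function(x, z) (x - z)^2)
      den <- outer(a, c, `+`)
      D <- num
      nz <- den > 0
      D[nz] <- num[nz] / den[nz]
      D[!nz] <- 0
      exp(-sigma * D)
    },
    stop("unknown kernel type: ", type, call. = FALSE)
  )
}

#' Build the per-feature kernel stack
#'
#' Computes one Gram block per (feature, kernel type) pair: with `d` features
#' and `kappa` kernel types this yields `b = d * kappa` blocks. Blocks are
#' ordered feature-major: flat index `(m - 1) * kappa + t` for feature `m`
#' and kernel type `t` (in spec order). The blocks are stored column-wise in
#' a single `(n_row * n_col) x b` matrix for fast weighted aggregation.
#'
#' @param X_rows,X_cols numeric matrices (samples x features) sharing the
#'   same feature count; entries must be finite and non-negative.
#' @param spec a [kernel_spec()].
#' @return an object of class `kernel_stack` with elements `Kmat`
#'   (vectorized Gram blocks as columns), `n_row`, `n_col`, `d`,
#'   `kernel_types`, `sigma`, and `index_map` (data.frame mapping flat block
#'   index to feature and kernel type).
#' @export
build_kernel_stack <- function(X_rows, X_cols = X_rows, spec = kernel_spec()) {
  X_rows <- as.matrix(X_rows); X_cols <- as.matrix(X_cols)
  if (ncol(X_rows) != ncol(X_cols))
    stop("X_rows and X_cols must share the same number of features",
         call. = FALSE)
  .check_nonneg(X_rows, .what = "feature matrix")
  .check_nonneg(X_cols, .what = "feature matrix")
  d <- ncol(X_rows)
  types <- spec$kernel_types
  kappa <- length(types)
  b <- d * kappa
  n_row <- nrow(X_rows); n_col <- nrow(X_cols)
  square <- n_row == n_col && isTRUE(all.equal(X_rows, X_cols,
                                               check.attributes = FALSE))
  Kmat <- matrix(0, n_row * n_col, b)
  for (m in seq_len(d)) {
    a <- X_rows[, m]; cc <- X_cols[, m]
    for (t in seq_along(types)) {
      G <- .gram_block(a, cc, types[t], spec$sigma)
      if (square) G <- (G + t(G)) / 2  # absorb floating-point asymmetry
      Kmat[, (m - 1L) * kappa + t] <- as.vector(G)
    }
  }
  index_map <- data.frame(
    block   = seq_len(b),
    feature = rep(seq_len(d), each = kappa),
    type    = rep(types, d),
    stringsAsFactors = FALSE
  )
  structure(list(Kmat = Kmat, n_row = n_row, n_col = n_col, d = d,
                 kernel_types = types, sigma = spec$sigma,
                 index_map = index_map, square = square),
            class = "kernel_stack")
}

#' Number of blocks in a kernel stack
#' @param stack a `kernel_stack`.
#' @return integer `b = d * kappa`.
#' @export
n_blocks <- function(stack) ncol(stack$Kmat)

#' Extract one Gram block from a stack
#' @param stack a `kernel_stack`.
#' @param block flat block index in `1..b`.
#' @return the `n_row x n_col` Gram matrix of that block.
#' @export
get_gram <- function(stack, block) {
  matrix(stack$Kmat[, block], stack$n_row, stack$n_col)
}

#' Aggregate the kernel stack under non-negative weights
#'
#' Returns the weighted sum of Gram blocks, `sum_m alpha_m K_m` — the
#' effective kernel of the multiple-kernel model. Exactly linear in `alpha`;
#' positive semidefinite for `alpha >= 0` when the stack is a
#' self-similarity stack, since every base kernel is PSD on non-negative
#' scalars.
#'
#' @param stack a `kernel_stack`.
#' @param alpha non-negative numeric vector of length `n_blocks(stack)`.
#' @return an `n_row x n_col` Gram matrix.
#' @export
aggregate_kernel <- function(stack, alpha) {
  if (length(alpha) != n_blocks(stack))
    stop("alpha length must equal the number of kernel blocks",
         call. = FALSE)
  if (any(!is.finite(alpha)))
    stop("alpha must be finite", call. = FALSE)
  if (any(alpha < 0))
    stop("alpha must be non-negative", call. = FALSE)
  matrix(stack$Kmat %*% alpha, stack$n_row, stack$n_col)
}
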