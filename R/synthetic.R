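# Synthetic benchmark generators. Both classic benchmarks are 50-dimensional
# with 100 samples per class, and all features are min-max normalized to
# [0, 1] so they behave like the non-negative, histogram-like features the
# classifier targets.

.minmax_01 <- function(X) {
  mn <- apply(X, 2, min); mx <- apply(X, 2, max)
  rng <- mx - mn
  rng[rng == 0] <- 1
  sweep(sweep(X, 2, mn, `-`), 2, rng, `/`)
}

# random orthonormal columns via QR of a Gaussian matrix, sign-fixed so the
# draw is deterministic given the RNG stream
.random_orthonormal <- function(nrow, ncol) {
  Q <- qr.Q(qr(matrix(stats::rnorm(nrow * nrow), nrow, nrow)))
  Q[, seq_len(ncol), drop = FALSE]
}

# random rotation: orthogonal matrix with determinant +1
.random_rotation <- function(dim) {
  Q <- qr.Q(qr(matrix(stats::rnorm(dim * dim), dim, dim)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Linearly separable two-subspace data
#'
#' Samples two classes from two distinct linear subspaces of the ambient
#' space: class +1 from the span of a random orthonormal basis `U1` and
#' class -1 from `U2 = T U1` with `T` a random rotation. Subspace
#' coefficients are i.i.d. uniform on `[0, 1]`, so each class occupies the
#' convex cone spanned by its basis; two random rank-`ambient_dim / 2`
#' cones in general position admit a separating hyperplane, which makes
#' the benchmark genuinely linearly separable (and keeps the raw features
#' closer to the non-negative, histogram-like regime the classifier
#' targets). The subspace rank defaults to half the ambient dimension so
#' the two rotated subspaces are genuinely distinct. Features are min-max
#' normalized to `[0, 1]`.
#'
#' @param ambient_dim ambient feature dimension (default 50).
#' @param n_per_class samples per class (default 100).
#' @param rank subspace rank (default `ambient_dim / 2`).
#' @param seed integer RNG seed.
#' @return list with `X` (`2 * n_per_class x ambient_dim` matrix in
#'   `[0, 1]`), `y` (-1/+1 labels), and `raw` (the pre-normalization
#'   samples, useful for geometric checks) plus the generating bases
#'   `U1`, `U2`.
#' @export
gen_linear_subspace_data <- function(ambient_dim = 50, n_per_class = 100,
                                     rank = ambient_dim %/% 2, seed = 1) {
  stopifnot(ambient_dim >= 2, n_per_class >= 1,
            rank >= 1, rank <= ambient_dim)
  set.seed(seed)
  U1 <- .random_orthonormal(ambient_dim, rank)
  T_rot <- .random_rotation(ambient_dim)
  U2 <- T_rot %*% U1
  Q1 <- matrix(stats::runif(rank * n_per_class), rank, n_per_class)
  Q2 <- matrix(stats::runif(rank * n_per_class), rank, n_per_class)
  raw <- rbind(t(U1 %*% Q1), t(U2 %*% Q2))
  X <- .minmax_01(raw)
  colnames(X) <- paste0("f", seq_len(ambient_dim))
  list(X = X, y = rep(c(1, -1), each = n_per_class), raw = raw,
       U1 = U1, U2 = U2)
}

#' Nonlinearly separable ball-versus-shell data
#'
#' Class +1 is sampled uniformly from the ball of radius `inner_radius`;
#' class -1 uniformly from the shell between `inner_radius` and
#' `outer_radius` around the same center. Uniformity is obtained as a
#' uniform direction on the sphere times a radius drawn with density
#' proportional to `r^(dim - 1)` on the appropriate interval. Features are
#' min-max normalized to `[0, 1]`.
#'
#' @param ambient_dim ambient dimension (default 50).
#' @param inner_radius ball radius / shell inner radius (default 0.5).
#' @param outer_radius shell outer radius (default 1).
#' @param n_per_class samples per class (default 100).
#' @param seed integer RNG seed.
#' @return list with `X` (normalized), `y` (-1/+1), and `raw`
#'   (pre-normalization coordinates).
#' @export
gen_sphere_shell_data <- function(ambient_dim = 50, inner_radius = 0.5,
                                  outer_radius = 1.0, n_per_class = 100,
                                  seed = 1) {
  stopifnot(ambient_dim >= 2, n_per_class >= 1,
            inner_radius > 0, inner_radius < outer_radius)
  set.seed(seed)
  unit_dirs <- function(n) {
    G <- matrix(stats::rnorm(n * ambient_dim), n, ambient_dim)
    G / sqrt(rowSums(G^2))
  }
  # uniform in ball: r = R * u^(1/dim)
  r1 <- inner_radius * stats::runif(n_per_class)^(1 / ambient_dim)
  # uniform in shell: r = (a^dim + u * (b^dim - a^dim))^(1/dim)
  a_d <- inner_radius^ambient_dim; b_d <- outer_radius^ambient_dim
  r2 <- (a_d + stats::runif(n_per_class) * (b_d - a_d))^(1 / ambient_dim)
  raw <- rbind(unit_dirs(n_per_class) * r1, unit_dirs(n_per_class) * r2)
  X <- .minmax_01(raw)
  colnames(X) <- paste0("f", seq_len(ambient_dim))
  list(X = X, y = rep(c(1, -1), each = n_per_class), raw = raw)
}

#' Informative-feature fixture data
#'
#' A controlled fixture for feature-recovery studies: the first
#' `n_informative` features carry a between-class mean shift of `effect`
#' standard deviations; the remaining features are i.i.d. noise with no
#' class association. Features are min-max normalized to `[0, 1]`.
#'
#' @param d total feature count.
#' @param n_informative number of signal-carrying features (first
#'   `n_informative` columns).
#' @param n_per_class samples per class.
#' @param effect class-mean separation of the informative features in
#'   standard-deviation units.
#' @param seed integer RNG seed.
#' @return list with `X`, `y` (-1/+1, exactly balanced) and
#'   `informative` (the informative column indices).
#' @export
gen_informative_feature_data <- function(d = 50, n_informative = 5,
                                         n_per_class = 50, effect = 2,
                                         seed = 1) {
  if (n_informative < 1 || n_informative > d)
    stop("need 1 <= n_informative <= d", call. = FALSE)
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  set.seed(seed)
  n <- 2L * n_per_class
  y <- rep(c(1, -1), each = n_per_class)
  X <- matrix(stats::rnorm(n * d), n, d)
  shift <- ifelse(y > 0, effect / 2, -effect / 2)
  X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] + shift
  X <- .minmax_01(X)
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = y, informative = seq_len(n_informative))
}
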