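# Independent brute-force oracles used across the test files. These stay
# deliberately naive (explicit loops, direct formulas) so they share no code
# path with the implementation.

brute_scalar_kernel <- function(type, a, c, sigma = 0.5) {
  stopifnot(length(a) == 1L, length(c) == 1L)
  if (type == "linear") return(a * c)
  if (type == "hik") return(min(a, c))
  D <- switch(type,
    rbf_euc  = (a - c) * (a - c),
    rbf_emd  = abs(a - c),
    rbf_chi2 = if (a + c == 0) 0 else (a - c)^2 / (a + c)
  )
  exp(-sigma * D)
}

brute_gram <- function(type, a_vec, c_vec, sigma = 0.5) {
  G <- matrix(0, length(a_vec), length(c_vec))
  for (i in seq_along(a_vec))
    for (j in seq_along(c_vec))
      G[i, j] <- brute_scalar_kernel(type, a_vec[i], c_vec[j], sigma)
  G
}

# weighted sum of Gram blocks by explicit accumulation
brute_aggregate <- function(stack, alpha) {
  K <- matrix(0, stack$n_row, stack$n_col)
  for (bk in seq_len(ncol(stack$Kmat)))
    K <- K + alpha[bk] * matrix(stack$Kmat[, bk], stack$n_row, stack$n_col)
  K
}

# decision function by explicit double loop over samples and blocks
brute_decision <- function(model, X_new) {
  Xn <- mklfs:::.minmax_apply(as.matrix(X_new), model$norm_bounds)
  Xt <- model$X_train
  types <- model$spec$kernel_types
  kappa <- length(types)
  d <- ncol(Xt)
  out <- numeric(nrow(Xn))
  for (i in seq_len(nrow(Xn))) {
    acc <- 0
    for (j in seq_len(nrow(Xt))) {
      kij <- 0
      for (m in seq_len(d)) {
        for (t in seq_along(types)) {
          w <- model$alpha[(m - 1L) * kappa + t]
          if (w > 0)
            kij <- kij + w * brute_scalar_kernel(types[t], Xn[i, m],
                                                 Xt[j, m],
                                                 model$spec$sigma)
        }
      }
      acc <- acc + model$svm$coefs[j] * kij
    }
    out[i] <- acc + model$svm$intercept
  }
  out
}

# exact SVM dual optimum via kernlab's interior-point QP (independent of
# the libsvm route used by the implementation)
ipop_dual_value <- function(K, y, C) {
  n <- length(y)
  H <- (y %o% y) * K
  r <- kernlab::ipop(c = rep(-1, n), H = H + diag(1e-10, n),
                     A = matrix(y, 1), b = 0,
                     l = rep(0, n), u = rep(C, n), r = 0)
  beta <- kernlab::primal(r)
  sum(beta) - 0.5 * drop(crossprod(beta * y, K %*% (beta * y)))
}

svm_dual_value <- function(sol, K) {
  sum(sol$beta) - 0.5 * drop(crossprod(sol$coefs, K %*% sol$coefs))
}

# tiny non-negative labeled dataset, linearly separable on feature 1
toy_separable <- function(n_per_class = 5, seed = 42) {
  set.seed(seed)
  X <- cbind(c(stats::runif(n_per_class, 0.7, 1.0),
               stats::runif(n_per_class, 0.0, 0.3)),
             stats::runif(2 * n_per_class))
  list(X = X, y = rep(c(1, -1), each = n_per_class))
}
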