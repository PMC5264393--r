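#' Training configuration
#'
#' Hyperparameters of the joint objective and of the alternating optimizer.
#' The joint objective minimized is
#' \deqn{\tfrac12 \|f\|_H^2 + C \sum_j \max(0, 1 - y_j f(x_j)) +
#'   \lambda \|\alpha\|_1,\qquad \alpha \ge 0,}
#' where the RKHS norm is taken under the aggregated kernel
#' \eqn{k_\alpha = \sum_m \alpha_m k_m}.
#'
#' @param C positive SVM trade-off (default 10).
#' @param lam non-negative l1 weight on the kernel weights (default 1).
#' @param max_outer_iters cap on alternating (outer) iterations (default 100).
#' @param rel_tol relative objective-change convergence tolerance
#'   (default 1e-4).
#' @param armijo_c sufficient-decrease constant in (0, 1) (default 1e-4).
#' @param backtrack step shrink factor in (0, 1) (default 0.5).
#' @param init_step initial gradient step size (default 1).
#' @param min_step step underflow floor; backtracking below this signals
#'   stagnation (default 1e-12).
#' @param svm_tol tolerance passed to the inner SVM dual solver.
#' @return an object of class `train_config`.
#' @export
train_config <- function(C = 10, lam = 1, max_outer_iters = 100L,
                         rel_tol = 1e-4, armijo_c = 1e-4, backtrack = 0.5,
                         init_step = 1.0, min_step = 1e-12,
                         svm_tol = 1e-6) {
  stopifnot(C > 0, lam >= 0, max_outer_iters >= 1,
            rel_tol > 0, armijo_c > 0, armijo_c < 1,
            backtrack > 0, backtrack < 1, init_step > 0)
  structure(list(C = C, lam = lam,
                 max_outer_iters = as.integer(max_outer_iters),
                 rel_tol = rel_tol, armijo_c = armijo_c,
                 backtrack = backtrack, init_step = init_step,
                 min_step = min_step, svm_tol = svm_tol),
            class = "train_config")
}

.check_labels <- function(y) {
  if (!all(y %in% c(-1, 1)))
    stop("labels must be coded -1/+1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("degenerate labels: both classes must be present", call. = FALSE)
  invisible(NULL)
}

#' Solve the SVM subproblem on a precomputed kernel
#'
#' With the kernel weights fixed, the max-margin subproblem is a standard
#' hinge-loss SVM on the aggregated Gram matrix. It is solved in the dual by
#' libsvm (`e1071::svm`): the PSD Gram matrix is factored through its
#' symmetric eigendecomposition `K = V D V'` and the rows of `V D^(1/2)`
#' are passed as explicit features under a linear kernel, which poses
#' exactly the same dual problem as the precomputed kernel. The returned
#' dual coefficients satisfy the box constraint `0 <= beta_j <= C` and the
#' equality `sum_j beta_j y_j = 0`; training decision values are
#' `f_i = sum_j beta_j y_j K_ij + intercept`.
#'
#' Before solving, small negative eigenvalue mass (from floating-point
#' accumulation in the weighted kernel sum) is tolerated up to
#' `1e-8 * trace(K)`; a clearly indefinite kernel is an error.
#'
#' @param K symmetric positive semidefinite `n x n` Gram matrix.
#' @param y numeric -1/+1 labels of length `n`.
#' @param C positive box constraint.
#' @param svm_tol solver tolerance.
#' @param check_psd verify positive semidefiniteness by an eigenvalue check
#'   before solving. The alternating optimizer disables this for kernels it
#'   aggregates itself, which are PSD by construction (non-negative weights
#'   over PSD blocks).
#' @return an object of class `svm_solution`: `beta` (length `n`, in
#'   `[0, C]`), `intercept`, `support_idx`, `labels`, and `coefs`
#'   (`beta * y`, the expansion coefficients).
#' @export
solve_svm_subproblem <- function(K, y, C = 10, svm_tol = 1e-4,
                                 check_psd = TRUE) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square", call. = FALSE)
  n <- nrow(K)
  if (length(y) != n) stop("length(y) must match dim(K)", call. = FALSE)
  .check_labels(y)

  K <- (K + t(K)) / 2
  tr <- sum(diag(K))
  if (tr <= 0) {
    # all-zero kernel: decision is intercept only; predict the majority
    # class (positive on ties)
    maj <- if (sum(y > 0) >= sum(y < 0)) 1 else -1
    return(structure(list(beta = numeric(n), intercept = maj,
                          support_idx = integer(0), labels = y,
                          coefs = numeric(n)),
                     class = "svm_solution"))
  }
  # eigenfactor; the eigenvalues double as the PSD guard (clip tiny
  # negative mass, refuse real indefiniteness)
  e <- eigen(K, symmetric = TRUE)
  if (check_psd && min(e$values) < -1e-8 * tr)
    stop("kernel matrix is not positive semidefinite", call. = FALSE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)

  fit <- e1071::svm(x = L, y = factor(y, levels = c(-1, 1)),
                    scale = FALSE, kernel = "linear", cost = C,
                    tolerance = svm_tol)
  sv <- fit$index
  cf <- as.vector(fit$coefs)         # alpha_i * (internal +-1 coding)
  u <- numeric(n)                    # u_i = beta_i * y_i
  u[sv] <- cf
  b0 <- -fit$rho                     # libsvm decision: sum coef*K - rho
  # libsvm's internal coding may be a global sign flip of y; recover the
  # flip from dual feasibility (beta = s * y * coefs must be >= 0)
  s <- if (any(y[sv] * cf < -1e-8 * C)) -1 else 1
  u <- s * u
  b0 <- s * b0
  beta <- u * y
  beta[beta < 0 & beta > -1e-10 * C] <- 0
  beta <- pmin(beta, C)
  structure(list(beta = beta, intercept = b0,
                 support_idx = which(beta > 0), labels = y, coefs = u),
            class = "svm_solution")
}

#' Joint objective value
#'
#' Evaluates the regularized max-margin objective at a given weight vector
#' and SVM solution: RKHS-norm term `0.5 * u' K u` (with `u = beta * y`),
#' hinge losses scaled by `C`, and the l1 penalty `lam * sum(alpha)` (equal
#' to `lam * ||alpha||_1` on the non-negative orthant).
#'
#' @param stack self-similarity `kernel_stack`.
#' @param alpha non-negative weight vector of length `n_blocks(stack)`.
#' @param svm `svm_solution` fitted on `aggregate_kernel(stack, alpha)`.
#' @param y -1/+1 labels.
#' @param cfg a [train_config()].
#' @return finite scalar objective value.
#' @export
joint_objective <- function(stack, alpha, svm, y, cfg = train_config()) {
  if (any(alpha < 0) || any(!is.finite(alpha)))
    stop("alpha must be finite and non-negative", call. = FALSE)
  K <- aggregate_kernel(stack, alpha)
  u <- svm$coefs
  f <- drop(K %*% u) + svm$intercept
  0.5 * drop(crossprod(u, K %*% u)) +
    cfg$C * sum(pmax(0, 1 - y * f)) +
    cfg$lam * sum(alpha)
}

#' Gradient of the joint objective in the kernel weights
#'
#' At the dual optimum of the SVM subproblem the margin term of the
#' objective has the reduced-gradient form
#' `-0.5 * sum_{ij} beta_i beta_j y_i y_j [K_m]_{ij}` per kernel block,
#' the standard result for the SVM dual value differentiated with respect to
#' kernel weights; the l1 term contributes `lam` to every component on the
#' non-negative orthant.
#'
#' @param stack self-similarity `kernel_stack`.
#' @param svm `svm_solution` at the current weights.
#' @param y -1/+1 labels (must match `svm$labels`).
#' @param lam non-negative l1 weight.
#' @return gradient vector of length `n_blocks(stack)`.
#' @export
grad_alpha <- function(stack, svm, y, lam = 1) {
  if (length(svm$coefs) != stack$n_row)
    stop("svm solution size does not match the kernel stack", call. = FALSE)
  u <- svm$coefs                       # beta * y
  U <- as.vector(tcrossprod(u))        # vectorized u u'
  drop(-0.5 * crossprod(stack$Kmat, U)) + lam
}

#' Projection onto the non-negative orthant
#'
#' Elementwise `max(v, 0)`: the Euclidean projection enforcing the
#' feasibility constraint on the kernel weights. Idempotent.
#'
#' @param v numeric vector.
#' @return projected vector.
#' @export
project_nonneg <- function(v) {
  if (any(!is.finite(v))) stop("v must be finite", call. = FALSE)
  pmax(v, 0)
}

#' Projected-gradient step with Armijo backtracking
#'
#' Starting from `cfg$init_step`, the step size is shrunk by `cfg$backtrack`
#' until the projected point `alpha+ = max(alpha - eta * grad, 0)` achieves
#' the sufficient decrease
#' `J(alpha+) <= J(alpha) + armijo_c * grad' (alpha+ - alpha)`. If the step
#' underflows `cfg$min_step` (a stationary or stalled point), the current
#' point is returned with `step = 0`.
#'
#' @param alpha current feasible weights.
#' @param grad gradient at `alpha`.
#' @param eval_fn function taking a feasible weight vector and returning the
#'   joint objective there (with the SVM subproblem re-solved).
#' @param cfg a [train_config()].
#' @param f0 optional precomputed `eval_fn(alpha)`.
#' @return list with `alpha` (the accepted point), `step` (accepted step
#'   size, 0 on stagnation) and `objective` (objective at the accepted
#'   point).
#' @export
armijo_step <- function(alpha, grad, eval_fn, cfg = train_config(),
                        f0 = NULL) {
  if (is.null(f0)) f0 <- eval_fn(alpha)
  eta <- cfg$init_step
  while (eta >= cfg$min_step) {
    cand <- project_nonneg(alpha - eta * grad)
    if (all(cand == alpha)) break  # projection fixed point: no move possible
    fc <- eval_fn(cand)
    if (fc <= f0 + cfg$armijo_c * sum(grad * (cand - alpha)))
      return(list(alpha = cand, step = eta, objective = fc))
    eta <- eta * cfg$backtrack
  }
  list(alpha = alpha, step = 0, objective = f0)
}

#' Alternating optimization of the joint objective
#'
#' Alternates between (i) solving the SVM dual on the aggregated kernel at
#' the current weights and (ii) a projected-gradient Armijo step on the
#' weights, until the relative objective change drops below `cfg$rel_tol`
#' or `cfg$max_outer_iters` is reached. Weights start uniform at `1/b`.
#' The recorded objective trace is non-increasing by construction; the
#' combination of the l1 penalty and projection produces exact zeros on
#' inactive kernel blocks.
#'
#' @param stack self-similarity `kernel_stack` built on the training data.
#' @param y -1/+1 labels.
#' @param cfg a [train_config()].
#' @param alpha0 optional initial weights (default uniform `1/b`).
#' @return list with `state` (class `mkl_state`: `alpha`,
#'   `objective_trace`, `n_outer`, `converged`, `stalled`) and `svm` (the
#'   final `svm_solution`, consistent with `alpha`).
#' @export
fit_alternating <- function(stack, y, cfg = train_config(), alpha0 = NULL) {
  if (!isTRUE(stack$square))
    stop("fit_alternating requires a self-similarity kernel stack",
         call. = FALSE)
  .check_labels(y)
  b <- n_blocks(stack)
  alpha <- if (is.null(alpha0)) rep(1 / b, b) else project_nonneg(alpha0)

  eval_at <- function(a) {
    sv <- solve_svm_subproblem(aggregate_kernel(stack, a), y, C = cfg$C,
                               svm_tol = cfg$svm_tol, check_psd = FALSE)
    list(svm = sv, value = joint_objective(stack, a, sv, y, cfg))
  }

  cur <- eval_at(alpha)
  trace <- cur$value
  converged <- FALSE
  stalled <- FALSE
  n_outer <- 0L
  # warm-started Armijo: begin each line search near twice the previously
  # accepted step, so backtracking stays short once the step scale is known
  eta_init <- cfg$init_step
  for (it in seq_len(cfg$max_outer_iters)) {
    n_outer <- it
    g <- grad_alpha(stack, cur$svm, y, lam = cfg$lam)
    # the line search re-solves the SVM at each trial point, so the
    # accepted objective is the true joint value and the trace is monotone
    last_eval <- NULL
    cfg_it <- cfg
    cfg_it$init_step <- eta_init
    step <- armijo_step(alpha, g, function(a) {
      last_eval <<- eval_at(a)
      last_eval$value
    }, cfg_it, f0 = cur$value)
    if (step$step == 0) { stalled <- TRUE; converged <- TRUE; break }
    prev_val <- cur$value
    alpha <- step$alpha
    cur <- last_eval  # armijo_step returns upon accepting the last eval
    eta_init <- min(max(2 * step$step, cfg$min_step * 1e3), 1e8)
    trace <- c(trace, cur$value)
    if (abs(prev_val - cur$value) <= cfg$rel_tol * max(1, abs(prev_val))) {
      converged <- TRUE
      break
    }
  }
  state <- structure(list(alpha = alpha, objective_trace = trace,
                          n_outer = n_outer, converged = converged,
                          stalled = stalled),
                     class = "mkl_state")
  list(state = state, svm = cur$svm)
}
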