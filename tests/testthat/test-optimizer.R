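test_that("two-point identity-kernel SVM is symmetric with zero intercept", {
  sol <- solve_svm_subproblem(diag(2), c(1, -1), C = 100)
  expect_equal(sol$beta[1], sol$beta[2], tolerance = 1e-6)
  expect_equal(sol$intercept, 0, tolerance = 1e-6)
  expect_equal(sum(sol$beta * c(1, -1)), 0, tolerance = 1e-8)
})

test_that("svm dual solution satisfies its constraints and separates toy data", {
  toy <- toy_separable()
  K <- tcrossprod(toy$X)   # linear kernel on the raw features
  sol <- solve_svm_subproblem(K, toy$y, C = 10)
  expect_true(all(sol$beta >= 0))
  expect_true(all(sol$beta <= 10 + 1e-8))
  expect_equal(sum(sol$beta * toy$y), 0, tolerance = 1e-6)
  f <- drop(K %*% sol$coefs) + sol$intercept
  expect_equal(sign(f), toy$y)   # separable: zero training error
})

test_that("svm dual value matches an interior-point QP oracle", {
  skip_if_not_installed("kernlab")
  set.seed(21)
  X <- matrix(runif(8), 4, 2)
  K <- tcrossprod(X) + diag(0.5, 4)
  y <- c(1, 1, -1, -1)
  sol <- solve_svm_subproblem(K, y, C = 5, svm_tol = 1e-10)
  expect_equal(svm_dual_value(sol, K), ipop_dual_value(K, y, C = 5),
               tolerance = 1e-6)
})

test_that("svm subproblem validates its inputs", {
  expect_error(solve_svm_subproblem(matrix(1, 2, 3), c(1, -1)), "square")
  expect_error(solve_svm_subproblem(diag(2), c(1, 2)), "-1/\\+1")
  expect_error(solve_svm_subproblem(diag(2), c(1, 1)), "degenerate")
  # clearly indefinite kernel is refused
  expect_error(solve_svm_subproblem(matrix(c(1, 2, 2, 1), 2), c(1, -1)),
               "semidefinite")
})

test_that("zero kernel falls back to a majority-class constant decision", {
  sol <- solve_svm_subproblem(matrix(0, 4, 4), c(1, 1, 1, -1), C = 10)
  expect_equal(sol$beta, numeric(4))
  expect_equal(sol$intercept, 1)
})

test_that("joint objective decomposes into its three terms", {
  set.seed(31)
  X <- matrix(runif(12), 4, 3)
  y <- c(1, -1, 1, -1)
  stack <- build_kernel_stack(X, X, kernel_spec(c("linear", "hik")))
  b <- n_blocks(stack)
  alpha <- runif(b)
  cfg <- train_config(C = 2, lam = 1.5)
  sol <- solve_svm_subproblem(aggregate_kernel(stack, alpha), y, C = cfg$C)

  # independent term-wise recomputation
  K <- brute_aggregate(stack, alpha)
  u <- sol$beta * y
  f <- as.vector(K %*% u) + sol$intercept
  manual <- 0.5 * sum(u * (K %*% u)) +
    cfg$C * sum(pmax(0, 1 - y * f)) + cfg$lam * sum(abs(alpha))
  expect_equal(joint_objective(stack, alpha, sol, y, cfg), manual,
               tolerance = 1e-10)

  # the l1 term vanishes at alpha = 0 and is linear in lambda
  sol0 <- solve_svm_subproblem(aggregate_kernel(stack, numeric(b)), y,
                               C = cfg$C)
  expect_equal(joint_objective(stack, numeric(b), sol0, y, cfg),
               cfg$C * sum(pmax(0, 1 - y * sol0$intercept)))
  cfg2 <- train_config(C = 2, lam = 3)
  expect_equal(joint_objective(stack, alpha, sol, y, cfg2) -
                 joint_objective(stack, alpha, sol, y, cfg),
               1.5 * sum(alpha), tolerance = 1e-10)

  expect_error(joint_objective(stack, -alpha, sol, y, cfg), "non-negative")
})

test_that("grad_alpha reduces to lambda on dead kernels and zero margins", {
  set.seed(32)
  X <- cbind(rep(0, 5), runif(5))   # feature 1 identically zero
  y <- c(1, 1, -1, -1, 1)
  stack <- build_kernel_stack(X, X, kernel_spec(c("linear", "hik")))
  fake <- structure(list(beta = numeric(5), coefs = numeric(5),
                         intercept = 0, labels = y,
                         support_idx = integer(0)),
                    class = "svm_solution")
  expect_equal(grad_alpha(stack, fake, y, lam = 2), rep(2, 4))

  sol <- solve_svm_subproblem(aggregate_kernel(stack, rep(1, 4)), y, C = 5)
  g <- grad_alpha(stack, sol, y, lam = 2)
  # feature 1's linear and hik blocks are zero Grams -> component = lambda
  expect_equal(g[1:2], c(2, 2))
})

test_that("grad_alpha matches central finite differences of the value function", {
  set.seed(33)
  X <- matrix(runif(10), 5, 2)
  y <- c(1, -1, 1, -1, 1)
  stack <- build_kernel_stack(X, X, kernel_spec(c("linear", "hik")))
  cfg <- train_config(C = 3, lam = 0.7, svm_tol = 1e-10)
  value_fn <- function(a) {
    sol <- solve_svm_subproblem(aggregate_kernel(stack, a), y, C = cfg$C,
                                svm_tol = cfg$svm_tol)
    joint_objective(stack, a, sol, y, cfg)
  }
  alpha <- rep(0.4, 4)
  sol <- solve_svm_subproblem(aggregate_kernel(stack, alpha), y, C = cfg$C,
                              svm_tol = cfg$svm_tol)
  g <- grad_alpha(stack, sol, y, lam = cfg$lam)
  h <- 1e-3   # below this, inner-solver noise dominates the quotient
  for (j in seq_len(4)) {
    e <- numeric(4); e[j] <- h
    fd <- (value_fn(alpha + e) - value_fn(alpha - e)) / (2 * h)
    expect_lt(abs(g[j] - fd) / max(abs(fd), 1e-8), 1e-3)
  }
})

test_that("projection onto the non-negative orthant clamps and is idempotent", {
  expect_equal(project_nonneg(c(-1, 2)), c(0, 2))
  expect_equal(project_nonneg(c(0, 0)), c(0, 0))
  set.seed(34)
  for (i in 1:20) {
    v <- rnorm(6)
    p <- project_nonneg(v)
    expect_true(all(p >= 0))
    expect_equal(project_nonneg(p), p)
  }
  expect_error(project_nonneg(c(1, NA)), "finite")
})

test_that("armijo backtracking accepts the first sufficient step and never ascends", {
  # 1-D quadratic (a - 1)^2: from a = 0.5 with exact gradient -1, the
  # initial step already satisfies the sufficient-decrease condition
  q <- function(a) (a - 1)^2
  cfg <- train_config(init_step = 0.25)
  st <- armijo_step(0.5, -1, q, cfg)
  expect_equal(st$step, 0.25)
  expect_equal(st$alpha, 0.75)

  # stationary point: no move
  st0 <- armijo_step(0.5, 0, q, cfg)
  expect_equal(st0$alpha, 0.5)
  expect_equal(st0$step, 0)

  # monotone by construction on a hard (concave) objective
  stc <- armijo_step(0.5, -1, function(a) -((a - 0.5)^2), cfg)
  expect_lte(stc$objective, 0)
})

test_that("alternating optimization keeps alpha feasible and the trace monotone", {
  set.seed(35)
  for (s in 1:10) {
    dat <- gen_informative_feature_data(d = 4, n_informative = 2,
                                        n_per_class = 8, effect = 2,
                                        seed = s)
    stack <- build_kernel_stack(dat$X, dat$X, kernel_spec())
    res <- fit_alternating(stack, dat$y, train_config(max_outer_iters = 30))
    expect_true(all(res$state$alpha >= 0))
    tr <- res$state$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("kappa = 1, lambda = 0 reduces to a plain linear SVM", {
  toy <- toy_separable(n_per_class = 10, seed = 44)
  stack <- build_kernel_stack(toy$X, toy$X, kernel_spec("linear"))
  res <- fit_alternating(stack, toy$y,
                         train_config(lam = 0, max_outer_iters = 50),
                         alpha0 = rep(1, 2))
  K <- aggregate_kernel(stack, res$state$alpha)
  f_ours <- drop(K %*% res$svm$coefs) + res$svm$intercept

  ref <- e1071::svm(toy$X, factor(toy$y, levels = c(-1, 1)),
                    scale = FALSE, kernel = "linear", cost = 10)
  pred_ref <- as.numeric(as.character(predict(ref, toy$X)))
  expect_equal(sign(f_ours), toy$y)
  expect_equal(sign(f_ours), pred_ref)
})

test_that("sparsity is non-increasing in lambda", {
  dat <- gen_informative_feature_data(d = 6, n_informative = 2,
                                      n_per_class = 12, effect = 2, seed = 2)
  stack <- build_kernel_stack(dat$X, dat$X, kernel_spec())
  nz <- vapply(c(0.1, 1, 10), function(l) {
    res <- fit_alternating(stack, dat$y, train_config(lam = l))
    sum(res$state$alpha > 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("degenerate labels are refused", {
  X <- matrix(runif(10), 5, 2)
  stack <- build_kernel_stack(X, X, kernel_spec("linear"))
  expect_error(fit_alternating(stack, rep(1, 5), train_config()),
               "degenerate")
})
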