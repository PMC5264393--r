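#' Joint kernel feature selection and max-margin classification
#'
#' Fits the sparse multiple-kernel SVM: features are min-max normalized to
#' `[0, 1]` (bounds taken from the training data), one Gram block is built
#' per (feature, kernel type) pair, and a non-negative l1-regularized weight
#' vector over the blocks is learned jointly with the SVM dual by
#' alternating optimization. Because each block sees a single feature, the
#' learned weights act as a feature- and kernel-selection readout.
#'
#' @param X numeric samples x features matrix (or data.frame) of
#'   non-negative finite values.
#' @param y class labels: either -1/+1 numerics or any two-level vector
#'   (the lexicographically smaller level maps to -1 unless
#'   `positive_label` is given).
#' @param spec a [kernel_spec()].
#' @param cfg a [train_config()].
#' @param positive_label optional label value to map to +1.
#' @return an object of class `mklfs_model` holding the normalized training
#'   data, labels, kernel spec, learned weights `alpha`, the inner SVM
#'   solution, the optimization `state`, per-feature normalization bounds
#'   and the label mapping.
#' @examples
#' set.seed(1)
#' dat <- gen_informative_feature_data(d = 8, n_informative = 2,
#'                                     n_per_class = 15, effect = 3, seed = 1)
#' fit <- mkl_fit(dat$X, dat$y)
#' table(predict(fit, dat$X), dat$y)
#' kernel_mean_weights(fit)
#' @export
mkl_fit <- function(X, y, spec = kernel_spec(), cfg = train_config(),
                    positive_label = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(X)) || any(X < 0))
    stop("features must be finite and non-negative", call. = FALSE)
  map <- .encode_labels(y, positive_label)
  if (length(map$y) != nrow(X))
    stop("length(y) must equal nrow(X)", call. = FALSE)
  .check_labels(map$y)

  bounds <- .minmax_bounds(X)
  Xn <- .minmax_apply(X, bounds)
  stack <- build_kernel_stack(Xn, Xn, spec)
  res <- fit_alternating(stack, map$y, cfg)
  K <- aggregate_kernel(stack, res$state$alpha)
  f_train <- drop(K %*% res$svm$coefs) + res$svm$intercept

  structure(list(X_train = Xn, y_train = map$y, spec = spec, cfg = cfg,
                 alpha = res$state$alpha, svm = res$svm, state = res$state,
                 norm_bounds = bounds, class_names = map$class_names,
                 decision_train = f_train,
                 feature_names = colnames(X)),
            class = "mklfs_model")
}

.encode_labels <- function(y, positive_label = NULL) {
  if (is.numeric(y) && all(y %in% c(-1, 1)) && is.null(positive_label))
    return(list(y = as.numeric(y), class_names = c(`-1` = -1, `1` = 1)))
  yc <- as.character(y)
  lev <- sort(unique(yc))
  if (length(lev) != 2L)
    stop("labels must take exactly two values", call. = FALSE)
  if (!is.null(positive_label)) {
    positive_label <- as.character(positive_label)
    if (!positive_label %in% lev)
      stop("positive_label not found among the labels", call. = FALSE)
    lev <- c(setdiff(lev, positive_label), positive_label)
  }
  list(y = ifelse(yc == lev[2L], 1, -1),
       class_names = stats::setNames(lev, c("-1", "1")))
}

.minmax_bounds <- function(X) {
  list(min = apply(X, 2, min), max = apply(X, 2, max))
}

# map to [0,1] with training bounds; zero-range features go to constant 0;
# out-of-range test values are clipped
.minmax_apply <- function(X, bounds) {
  rng <- bounds$max - bounds$min
  Xn <- sweep(X, 2, bounds$min, `-`)
  pos <- rng > 0
  Xn[, pos] <- sweep(Xn[, pos, drop = FALSE], 2, rng[pos], `/`)
  Xn[, !pos] <- 0
  pmin(pmax(Xn, 0), 1)
}

#' Decision values for new samples
#'
#' Evaluates the fitted decision function
#' `f(x) = sum_j beta_j y_j k_alpha(x_j, x) + intercept` on new samples,
#' after normalizing their features with the training min-max bounds
#' (clipped to `[0, 1]`).
#'
#' @param model a fitted `mklfs_model`.
#' @param X_new samples x features matrix with the training feature count.
#' @return numeric vector of decision values, one per row of `X_new`.
#' @export
decision_function <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  storage.mode(X_new) <- "double"
  if (ncol(X_new) != ncol(model$X_train))
    stop("X_new must have ", ncol(model$X_train), " features",
         call. = FALSE)
  if (any(!is.finite(X_new)) || any(X_new < 0))
    stop("features must be finite and non-negative", call. = FALSE)
  Xn <- .minmax_apply(X_new, model$norm_bounds)
  stack <- build_kernel_stack(Xn, model$X_train, model$spec)
  K <- aggregate_kernel(stack, model$alpha)   # n_new x n_train
  drop(K %*% model$svm$coefs) + model$svm$intercept
}

#' Predict class labels
#'
#' Sign of the decision value; an exact zero is assigned to the positive
#' class. Returns labels in the user's original coding.
#'
#' @param object a fitted `mklfs_model`.
#' @param X_new samples x features matrix.
#' @param ... unused.
#' @return vector of predicted class labels.
#' @export
predict.mklfs_model <- function(object, X_new, ...) {
  f <- decision_function(object, X_new)
  sign_lab <- ifelse(f >= 0, "1", "-1")
  out <- object$class_names[sign_lab]
  if (is.numeric(object$class_names)) out <- as.numeric(out)
  unname(out)
}

#' @export
print.mklfs_model <- function(x, ...) {
  d <- ncol(x$X_train)
  kappa <- length(x$spec$kernel_types)
  cat("Sparse multiple-kernel SVM\n")
  cat("  samples:", nrow(x$X_train), " features:", d,
      " kernel types:", kappa, " blocks:", d * kappa, "\n")
  cat("  nonzero kernel weights:", sum(x$alpha > 0), "of", length(x$alpha),
      "\n")
  cat("  outer iterations:", x$state$n_outer,
      " converged:", x$state$converged, "\n")
  invisible(x)
}

#' Kernel and feature weight summary
#'
#' Aggregates the learned block weights into two readouts: the mean weight
#' per kernel type (averaging each type's weights over all `d` features —
#' large values flag kernel types the data favor) and the per-feature
#' weight (summing each feature's weights over kernel types — nonzero
#' entries are the selected features).
#'
#' @param model a fitted `mklfs_model`.
#' @return an object of class `kernel_weight_summary`:
#'   `mean_weight_per_kernel_type` (named by kernel type),
#'   `per_feature_weight` and `selected_features` (indices with strictly
#'   positive total weight).
#' @export
kernel_mean_weights <- function(model) {
  im <- model$svm  # ensure fitted
  d <- ncol(model$X_train)
  types <- model$spec$kernel_types
  kappa <- length(types)
  A <- matrix(model$alpha, nrow = kappa, ncol = d)  # [type, feature]
  mw <- rowMeans(A)
  names(mw) <- types
  pf <- colSums(A)
  names(pf) <- model$feature_names %||% paste0("f", seq_len(d))
  structure(list(mean_weight_per_kernel_type = mw,
                 per_feature_weight = pf,
                 selected_features = unname(which(pf > 0))),
            class = "kernel_weight_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kernel_weight_summary <- function(x, ...) {
  cat("Mean kernel weight per kernel type:\n")
  print(round(x$mean_weight_per_kernel_type, 4))
  cat("Selected features:", length(x$selected_features), "\n")
  invisible(x)
}
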