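# Evaluation machinery: stratified k-fold CV with ACC/SEN/SPE/AUC,
# permutation significance testing, bootstrap accuracy distributions and a
# lambda-sensitivity sweep. The positive class is the label mapped to +1.

#' Confusion counts
#'
#' @param truth -1/+1 truth labels.
#' @param pred -1/+1 predicted labels.
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(tp = sum(truth == 1 & pred == 1),
                 fp = sum(truth == -1 & pred == 1),
                 tn = sum(truth == -1 & pred == -1),
                 fn = sum(truth == 1 & pred == -1)),
            class = "confusion_counts")
}

# Mann-Whitney AUC: probability a positive outscores a negative, ties 0.5
.rank_auc <- function(scores, truth) {
  pos <- truth == 1
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics
#'
#' Accuracy, sensitivity (true-positive rate) and specificity
#' (true-negative rate) from confusion counts, as percentages, plus the
#' rank-based AUC (the probability a random positive receives a higher
#' decision value than a random negative, ties counted half).
#'
#' @param counts a [confusion_counts()] object.
#' @param scores decision values (larger favors the positive class).
#' @param truth -1/+1 truth labels matching `scores`.
#' @return list with `acc`, `sen`, `spe` (percent) and `auc` (in
#'   `[0, 1]`).
#' @export
compute_metrics <- function(counts, scores, truth) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total != length(truth))
    stop("confusion counts inconsistent with truth length", call. = FALSE)
  if (counts$tp + counts$fn == 0 || counts$tn + counts$fp == 0)
    stop("undefined metric: a class is empty", call. = FALSE)
  list(acc = 100 * (counts$tp + counts$tn) / total,
       sen = 100 * counts$tp / (counts$tp + counts$fn),
       spe = 100 * counts$tn / (counts$tn + counts$fp),
       auc = .rank_auc(scores, truth))
}

# stratified fold assignment: shuffle within class, deal round-robin
.stratified_folds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("each class needs at least k samples for k folds", call. = FALSE)
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation
#'
#' Splits the samples into `k` class-stratified folds; for each fold the
#' model is fitted on the remaining folds (feature normalization bounds are
#' re-estimated on the training split only, so no information leaks into
#' the held-out fold) and scored on the held-out fold. Headline ACC/SEN/SPE
#' are pooled over the concatenated held-out predictions; per-fold
#' accuracies and kernel-weight summaries are also returned.
#'
#' @param X samples x features matrix of non-negative values.
#' @param y two-level labels (-1/+1 or any two values).
#' @param k number of folds (default 10).
#' @param spec a [kernel_spec()].
#' @param cfg a [train_config()].
#' @param seed integer seed controlling the fold assignment.
#' @return object of class `cv_result`: `acc`, `sen`, `spe` (pooled
#'   percentages), `auc`, `fold_accuracies` (percent), `folds` (fold id
#'   per sample), `scores` and `pred` per sample, `weight_summaries` (one
#'   [kernel_mean_weights()] per fold) and `convergence` (per-fold outer
#'   iterations, convergence flag and monotone-trace flag).
#' @export
stratified_kfold_cv <- function(X, y, k = 10, spec = kernel_spec(),
                                cfg = train_config(), seed = 1) {
  X <- as.matrix(X)
  map <- .encode_labels(y)
  yy <- map$y
  folds <- .stratified_folds(yy, k, seed)
  scores <- numeric(length(yy))
  pred <- numeric(length(yy))
  fold_acc <- numeric(k)
  wsum <- vector("list", k)
  conv <- data.frame(fold = seq_len(k), n_outer = NA_integer_,
                     converged = NA, monotone = NA)
  for (fd in seq_len(k)) {
    te <- folds == fd
    fit <- mkl_fit(X[!te, , drop = FALSE], yy[!te], spec, cfg)
    f <- decision_function(fit, X[te, , drop = FALSE])
    scores[te] <- f
    pred[te] <- ifelse(f >= 0, 1, -1)
    fold_acc[fd] <- 100 * mean(pred[te] == yy[te])
    wsum[[fd]] <- kernel_mean_weights(fit)
    tr <- fit$state$objective_trace
    conv$n_outer[fd] <- fit$state$n_outer
    conv$converged[fd] <- fit$state$converged
    conv$monotone[fd] <- all(diff(tr) <= 1e-8 * pmax(1, abs(tr[-length(tr)])))
  }
  m <- compute_metrics(confusion_counts(yy, pred), scores, yy)
  structure(list(acc = m$acc, sen = m$sen, spe = m$spe, auc = m$auc,
                 fold_accuracies = fold_acc, folds = folds,
                 scores = scores, pred = pred, truth = yy,
                 class_names = map$class_names,
                 weight_summaries = wsum, convergence = conv,
                 k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: ACC %.1f%%  SEN %.1f%%  SPE %.1f%%  AUC %.3f\n",
              x$k, x$acc, x$sen, x$spe, x$auc))
  invisible(x)
}

#' Permutation test of classifier significance
#'
#' Repeats the full cross-validated classification under `pi` random
#' permutations of the class labels and compares the null misclassification
#' rates with the observed one. The p-value is the portion of permuted runs
#' whose error is at most the observed error,
#' `p = #\{null error <= observed error\} / pi`; the add-one smoothed
#' variant `(count + 1) / (pi + 1)` is reported alongside.
#'
#' @param X,y,k,spec,cfg as in [stratified_kfold_cv()].
#' @param pi number of label permutations (default 100).
#' @param seed integer master seed; permutation draws and fold assignments
#'   derive sub-seeds from it.
#' @return object of class `permutation_result`: `p_value`,
#'   `p_value_smoothed`, `observed_error`, `null_errors` (length `pi`,
#'   fractions in `[0, 1]`) and `pi`.
#' @export
permutation_test <- function(X, y, k = 10, spec = kernel_spec(),
                             cfg = train_config(), pi = 100, seed = 1) {
  stopifnot(pi >= 1)
  obs <- stratified_kfold_cv(X, y, k, spec, cfg, seed = seed)
  observed_error <- 1 - obs$acc / 100
  yy <- .encode_labels(y)$y
  null_errors <- numeric(pi)
  for (i in seq_len(pi)) {
    sub_seed <- (seed + 104729L * i) %% .Machine$integer.max
    set.seed(sub_seed)
    y_perm <- sample(yy)
    cv <- stratified_kfold_cv(X, y_perm, k, spec, cfg, seed = sub_seed)
    null_errors[i] <- 1 - cv$acc / 100
  }
  n_le <- sum(null_errors <= observed_error)
  structure(list(p_value = n_le / pi,
                 p_value_smoothed = (n_le + 1) / (pi + 1),
                 observed_error = observed_error,
                 null_errors = null_errors, pi = pi,
                 observed_cv = obs),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (pi = %d): observed error %.3f, p = %.3f (smoothed %.3f)\n",
    x$pi, x$observed_error, x$p_value, x$p_value_smoothed))
  invisible(x)
}

#' Bootstrap accuracy distribution
#'
#' Each trial resamples all `n` subjects with replacement; the first 90% of
#' the resampled order trains the classifier and the remaining 10% is
#' classified. Trials whose train or test part contains a single class are
#' skipped and counted. Because subjects are resampled with replacement,
#' trials are i.i.d. and their accuracies form a distribution whose mean
#' and spread summarize the stability of the classifier.
#'
#' @param X,y,spec,cfg as in [stratified_kfold_cv()].
#' @param n_trials number of bootstrap trials (default 1000).
#' @param train_frac fraction of the resample used for training
#'   (default 0.9).
#' @param seed integer master seed.
#' @return object of class `bootstrap_result`: `trial_accuracies`
#'   (percent, one per completed trial), `mean`, `sd`, `n_trials`,
#'   `n_skipped`.
#' @export
bootstrap_eval <- function(X, y, n_trials = 1000, spec = kernel_spec(),
                           cfg = train_config(), train_frac = 0.9,
                           seed = 1) {
  stopifnot(n_trials >= 1, train_frac > 0, train_frac < 1)
  X <- as.matrix(X)
  yy <- .encode_labels(y)$y
  n <- length(yy)
  n_train <- floor(train_frac * n)
  accs <- numeric(0)
  n_skipped <- 0L
  for (i in seq_len(n_trials)) {
    set.seed((seed + 15485863L * i) %% .Machine$integer.max)
    idx <- sample(n, n, replace = TRUE)
    tr <- idx[seq_len(n_train)]
    te <- idx[(n_train + 1L):n]
    if (length(unique(yy[tr])) < 2L || length(unique(yy[te])) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    fit <- mkl_fit(X[tr, , drop = FALSE], yy[tr], spec, cfg)
    pred <- ifelse(decision_function(fit, X[te, , drop = FALSE]) >= 0, 1, -1)
    accs <- c(accs, 100 * mean(pred == yy[te]))
  }
  structure(list(trial_accuracies = accs,
                 mean = mean(accs), sd = stats::sd(accs),
                 n_trials = n_trials, n_skipped = n_skipped),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap (%d trials, %d skipped): accuracy %.1f%% +- %.1f\n",
              x$n_trials, x$n_skipped, x$mean,
              if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

#' Sensitivity sweep over the l1 weight lambda
#'
#' Runs the cross-validated pipeline once per candidate `lambda` and
#' tabulates accuracy and AUC, to assess how strongly results depend on the
#' sparsity trade-off.
#'
#' @param X,y,k,spec,cfg,seed as in [stratified_kfold_cv()]; `cfg$lam` is
#'   overridden per row.
#' @param lambdas positive numeric vector of l1 weights.
#' @return data.frame with columns `lambda`, `acc`, `auc`.
#' @export
lambda_sweep <- function(X, y, lambdas, k = 10, spec = kernel_spec(),
                         cfg = train_config(), seed = 1) {
  stopifnot(length(lambdas) >= 1, all(lambdas > 0))
  rows <- lapply(lambdas, function(l) {
    cfg_l <- cfg
    cfg_l$lam <- l
    cv <- stratified_kfold_cv(X, y, k, spec, cfg_l, seed = seed)
    data.frame(lambda = l, acc = cv$acc, auc = cv$auc)
  })
  do.call(rbind, rows)
}
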