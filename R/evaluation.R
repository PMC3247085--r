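# Metrics and evaluation protocols: positive-class precision/recall/F1,
# rank-based AUC, stratified k-fold cross-validation and learning curves
# over labeled-set sizes.

#' Precision, recall and F1 for the positive class
#'
#' @param y_true,y_pred Equal-length vectors with labels in `{+1, -1}`.
#' @return Named numeric vector `precision`, `recall`, `f1`; a zero
#'   denominator yields 0 with a warning.
#' @export
prf <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch between truth and prediction", call. = FALSE)
  }
  if (!all(c(y_true, y_pred) %in% c(-1, 1))) {
    stop("labels must be +1/-1", call. = FALSE)
  }
  tp <- sum(y_true > 0 & y_pred > 0)
  fp <- sum(y_true < 0 & y_pred > 0)
  fn <- sum(y_true > 0 & y_pred < 0)
  zdiv <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator in ", what, "; reporting 0", call. = FALSE)
      0
    } else num / den
  }
  p <- zdiv(tp, tp + fp, "precision")
  r <- zdiv(tp, tp + fn, "recall")
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' scores above a random negative, ties counted one half.
#'
#' @param y_true Labels in `{+1, -1}`, both classes present.
#' @param scores Numeric scores (larger = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("length mismatch", call. = FALSE)
  }
  pos <- y_true > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: within each class, shuffle and deal
# round-robin into n_folds
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < n_folds) {
      stop("stratification impossible: class ", cl, " has ", length(idx),
           " examples for ", n_folds, " folds", call. = FALSE)
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                  length(idx))
  }
  fold
}

# stratified subsample of size n (at least one per class when n >= 2)
stratified_sample <- function(y, n) {
  pos <- which(y > 0); neg <- which(y < 0)
  n_pos <- max(1L, min(length(pos), round(n * length(pos) / length(y))))
  n_neg <- n - n_pos
  if (n_neg < 1L || n_neg > length(neg)) {
    n_neg <- max(1L, min(length(neg), n_neg))
    n_pos <- n - n_neg
  }
  c(sample(pos, n_pos), sample(neg, n_neg))
}

# run one configured method on a labeled/pool split; returns the model
run_method <- function(method, X_l, y_l, X_pool, y_pool_gold, config) {
  oracle <- gold_oracle(if (length(y_pool_gold)) y_pool_gold else 1)
  fit <- switch(method,
    svm = run_supervised(X_l, y_l, config),
    rs = run_rs(X_l, y_l, X_pool, oracle, config),
    cluster = run_cluster(X_l, y_l, X_pool, config),
    bt = run_bt(X_l, y_l, X_pool, oracle, config),
    btda = run_btda(X_l, y_l, X_pool, oracle, config),
    stop("unknown method: ", method, call. = FALSE)
  )
  fit
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into seeded stratified folds; within each fold the
#' training portion is further divided into a small labeled set and an
#' unlabeled pool (per `n_labeled`), the configured method is run, and
#' positive-class precision, recall, F1 and AUC are measured on the
#' held-out fold. The aggregate is the unweighted mean over folds, as in
#' standard 10-fold protocol reporting.
#'
#' @param X Feature matrix. @param y Labels in `{+1, -1}`.
#' @param config A [run_config()]; its `method` is used.
#' @param n_folds Number of folds (default 10).
#' @param n_labeled Size of the labeled subset within each training
#'   portion (default 50); the remainder becomes the unlabeled pool.
#' @param seed Integer seed controlling folds and splits.
#' @return An object of class `ppi_eval_report`: list with `precision`,
#'   `recall`, `f1`, `auc` (fold means), `per_fold` (data frame),
#'   `n_folds`, `seed`, `config`.
#' @export
kfold_cv <- function(X, y, config, n_folds = 10L, n_labeled = 50L,
                     seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  fold <- stratified_folds(y, n_folds, seed)
  per <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test <- which(fold == k)
    train <- which(fold != k)
    set.seed(seed * 1000L + k)
    lab <- train[stratified_sample(y[train], min(n_labeled, length(train)))]
    pool <- setdiff(train, lab)
    fit <- run_method(config$method, X[lab, , drop = FALSE], y[lab],
                      X[pool, , drop = FALSE], y[pool], config)
    scores <- decision_value(fit$model, X[test, , drop = FALSE])
    m <- prf(y[test], ifelse(scores >= 0, 1, -1))
    per[[k]] <- data.frame(fold = k, precision = m[["precision"]],
                           recall = m[["recall"]], f1 = m[["f1"]],
                           auc = auc(y[test], scores))
  }
  per <- do.call(rbind, per)
  structure(list(precision = mean(per$precision), recall = mean(per$recall),
                 f1 = mean(per$f1), auc = mean(per$auc), per_fold = per,
                 n_folds = n_folds, seed = seed,
                 config = config_echo(config)),
            class = "ppi_eval_report")
}

#' @export
print.ppi_eval_report <- function(x, ...) {
  cat(sprintf(
    "<ppi_eval_report> %s | %d-fold | P = %.3f  R = %.3f  F1 = %.3f  AUC = %.3f\n",
    x$config$method, x$n_folds, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

#' Learning curves over labeled-set sizes
#'
#' For each size, the labeled set is sampled randomly (stratified so
#' both classes appear) and all remaining points form the unlabeled pool
#' on which the methods are evaluated transductively; results are
#' averaged over `n_runs` seeded repetitions. Sizes that leave no
#' unlabeled remainder are skipped with a warning. Oracle-labeled points
#' are excluded from the evaluation set of the method that queried them.
#'
#' @param X Feature matrix. @param y Labels.
#' @param methods Character vector of method names.
#' @param sizes Integer vector of labeled-set sizes.
#' @param configs Optional named list of `ppi_config`s (one per method);
#'   defaults are built with [run_config()] and the run seed.
#' @param n_runs Repetitions per size (default 10).
#' @param seed Base seed.
#' @return A data frame `size`, `method`, `mean_f1`, `sd_f1`, `n_runs`.
#' @export
learning_curve <- function(X, y, methods = c("svm", "bt", "btda"),
                           sizes = c(10L, 25L, 50L), configs = NULL,
                           n_runs = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  rows <- list()
  for (size in sizes) {
    if (size >= length(y)) {
      warning("size ", size, " leaves no unlabeled remainder; skipped",
              call. = FALSE)
      next
    }
    for (method in methods) {
      f1s <- numeric(n_runs)
      for (run in seq_len(n_runs)) {
        run_seed <- seed * 10000L + run
        set.seed(run_seed)
        lab <- stratified_sample(y, size)
        pool <- setdiff(seq_along(y), lab)
        config <- if (!is.null(configs) && !is.null(configs[[method]])) {
          configs[[method]]
        } else {
          run_config(method, seed = run_seed)
        }
        fit <- run_method(method, X[lab, , drop = FALSE], y[lab],
                          X[pool, , drop = FALSE], y[pool], config)
        eval_idx <- pool
        if (!is.null(fit$partition)) {
          # S_k holds 1-based indices into the pool
          eval_idx <- pool[setdiff(seq_along(pool), fit$partition$S_k)]
        }
        scores <- decision_value(fit$model, X[eval_idx, , drop = FALSE])
        f1s[run] <- prf(y[eval_idx], ifelse(scores >= 0, 1, -1))[["f1"]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, method = method, mean_f1 = mean(f1s),
        sd_f1 = stats::sd(f1s), n_runs = n_runs)
    }
  }
  if (!length(rows)) {
    return(data.frame(size = integer(), method = character(),
                      mean_f1 = numeric(), sd_f1 = numeric(),
                      n_runs = integer()))
  }
  do.call(rbind, rows)
}
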