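#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3); constant input is
#'   undefined and returns NA with a warning.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

# Stratified-by-target-quantile fold assignment: events sorted by target,
# folds dealt within consecutive blocks so every fold sees the full target
# range. Deterministic given the seed.
stratified_folds <- function(y, folds, seed) {
  n <- length(y)
  rng <- local({ set.seed(seed); function(k) sample.int(k) })
  ord <- order(y)
  fold <- integer(n)
  i <- 1L
  while (i <= n) {
    block <- ord[i:min(n, i + folds - 1L)]
    fold[block] <- rng(folds)[seq_along(block)]
    i <- i + folds
  }
  fold
}

#' Random-forest SEF regression with k-fold cross-validation
#'
#' Fits the package's regression random forest (bootstrap CART trees,
#' variance-reduction splits, sqrt(p) features per split) under
#' stratified-by-target-quantile fold assignment and reports out-of-fold
#' predictions, so no event contributes to the model that predicts it.
#' Missing feature values are imputed with the training-fold column median.
#' Feature importances (normalized impurity decrease) come from a final
#' model fit on the full data.
#'
#' @param x numeric feature matrix (rows = events).
#' @param y numeric targets (log2 SEF), finite.
#' @param folds number of CV folds (default 3).
#' @param ntree trees per forest (default 500).
#' @param mtry features tried per split (default floor(sqrt(p))).
#' @param min_node minimum node size (default 5).
#' @param seed integer seed; fixes fold assignment and all forest
#'   randomness.
#' @return `sef_model_report`: list with `oof` (out-of-fold predictions in
#'   input order), `fold` assignment, pooled `r`, per-fold `r_fold` and
#'   their mean `r_fold_mean`, `importance` (named, sums to 1),
#'   `hyperparameters`, `seed`.
#' @export
fit_cv <- function(x, y, folds = 3L, ntree = 500L, mtry = NULL,
                   min_node = 5L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(length(y) == n, all(is.finite(y)))
  if (n < folds) stop("need at least as many events as folds")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  fold <- stratified_folds(y, folds, seed)
  oof <- rep(NA_real_, n)
  r_fold <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    xtr <- impute_median(x[tr, , drop = FALSE])
    xte <- impute_median(x[te, , drop = FALSE], attr(xtr, "medians"))
    fit <- .rf_fit_predict(xtr, y[tr], xte, as.integer(ntree),
                           as.integer(mtry), as.integer(min_node),
                           as.integer(seed) + f)
    oof[te] <- fit$pred
    r_fold[f] <- if (stats::sd(fit$pred) > 0 && stats::sd(y[te]) > 0)
      stats::cor(y[te], fit$pred) else NA_real_
  }
  xall <- impute_median(x)
  full <- .rf_fit_predict(xall, y, xall[0, , drop = FALSE],
                          as.integer(ntree), as.integer(mtry),
                          as.integer(min_node), as.integer(seed))
  imp <- setNames(full$importance, colnames(x))
  r <- if (stats::sd(y) > 0 && stats::sd(oof) > 0) stats::cor(y, oof) else NA_real_
  structure(list(oof = oof, fold = fold, r = r, r_fold = r_fold,
                 r_fold_mean = mean(r_fold, na.rm = TRUE), importance = imp,
                 hyperparameters = list(folds = folds, ntree = ntree,
                                        mtry = mtry, min_node = min_node),
                 seed = seed),
            class = "sef_model_report")
}

#' @export
print.sef_model_report <- function(x, ...) {
  cat(sprintf("sef_model_report: %d events, %d-fold CV, pooled R = %.3f (per-fold mean %.3f)\n",
              length(x$oof), x$hyperparameters$folds, x$r, x$r_fold_mean))
  cat("top features:", paste(names(importances(x))[1:min(5, length(x$importance))],
                             collapse = ", "), "\n")
  invisible(x)
}

# Column-median imputation; medians optionally supplied (training fold).
impute_median <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(x, 2, stats::median, na.rm = TRUE)
    medians[!is.finite(medians)] <- 0
  }
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- medians[j]
  }
  attr(x, "medians") <- medians
  x
}

#' Ranked feature importances from a fitted report
#'
#' @param report a [fit_cv()] report.
#' @return named numeric vector, decreasing, summing to 1.
#' @export
importances <- function(report) {
  sort(report$importance, decreasing = TRUE)
}
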