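#' Stratified k-fold assignments
#'
#' Shuffles each class separately and deals its samples round-robin across
#' folds, so every sample lands in exactly one test fold and class
#' proportions are as even as integer arithmetic allows.
#'
#' @param labels class labels.
#' @param k_folds number of folds (>= 2).
#' @param stratified stratify on class (default TRUE); when stratified,
#'   `k_folds` must not exceed the smaller class count.
#' @param seed integer RNG seed.
#' @return integer vector of fold ids (1..k) per sample.
#' @export
make_folds <- function(labels, k_folds, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  if (k_folds < 2 || k_folds > n) .fail("`k_folds` must be in [2, n]")
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k_folds) {
        .fail("class '", cl, "' has fewer samples (", length(idx),
              ") than folds (", k_folds, ") under stratification")
      }
      fold[sample(idx)] <- rep_len(seq_len(k_folds), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k_folds), n)
  }
  fold
}

# train on K-submatrix and score a held-out block; shared by CV and grid
# search so fold assignments and kernels agree across hyperparameters
.cv_fold_scores <- function(K, y, fold, f, C, tol = 1e-3) {
  tr <- which(fold != f); te <- which(fold == f)
  sol <- .smo_solve(K[tr, tr, drop = FALSE], y[tr], C, tol)
  drop(K[te, tr, drop = FALSE] %*% (sol$alpha * y[tr]) + sol$b)
}

#' Grid search for SVM hyperparameters
#'
#' Evaluates mean cross-validated accuracy (at the zero-score cutoff) for
#' every `(C, sigma)` pair with identical fold assignments, and returns
#' the maximizer. Ties break toward smaller `C`, then larger `sigma`.
#'
#' @param x complete numeric training matrix.
#' @param labels class labels (`"cancer"`/`"normal"` or -1/+1).
#' @param c_grid candidate box constraints (default 0.1, 1, 10, 100).
#' @param sigma_grid candidate kernel widths; default a log2 grid centered
#'   on the median pairwise distance heuristic.
#' @param k_folds folds (default 20).
#' @param stratified stratify folds on class (default TRUE).
#' @param seed RNG seed controlling the fold assignment.
#' @return list with `best_C`, `best_sigma`, and `cv_table` (one row per
#'   grid pair with mean CV accuracy percent).
#' @export
grid_search_svm <- function(x, labels, c_grid = c(0.1, 1, 10, 100),
                            sigma_grid = NULL, k_folds = 20,
                            stratified = TRUE, seed = 1L) {
  if (length(c_grid) == 0 || (!is.null(sigma_grid) &&
                              length(sigma_grid) == 0)) {
    .fail("hyperparameter grids must be non-empty")
  }
  x <- as.matrix(x)
  y <- .encode_labels(labels)
  if (is.null(sigma_grid)) {
    set.seed(seed)
    s0 <- .sigma_heuristic(x)
    sigma_grid <- s0 * 2^seq(-2, 2)
  }
  fold <- make_folds(y, k_folds, stratified, seed)
  D <- .sqdist(x)
  grid <- expand.grid(C = c_grid, sigma = sigma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(grid))
  for (si in seq_along(sigma_grid)) {
    K <- exp(-D / (2 * sigma_grid[si]^2))
    for (ci in seq_along(c_grid)) {
      g <- (si - 1L) * length(c_grid) + ci
      correct <- 0L
      for (f in seq_len(k_folds)) {
        sc <- .cv_fold_scores(K, y, fold, f, c_grid[ci])
        pred <- ifelse(sc > 0, 1, -1)
        correct <- correct + sum(pred == y[fold == f])
      }
      acc[g] <- 100 * correct / length(y)
    }
  }
  grid$cv_accuracy <- acc
  # maximize accuracy; ties -> smaller C, then larger sigma
  ord <- order(-grid$cv_accuracy, grid$C, -grid$sigma)
  best <- grid[ord[1], ]
  list(best_C = best$C, best_sigma = best$sigma, cv_table = grid)
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Partitions the samples into `k_folds` stratified folds, trains on the
#' complement of each fold, scores the held-out fold at the zero cutoff,
#' and reports per-fold sensitivity, specificity and accuracy together
#' with their across-fold means and normal-approximation 95% confidence
#' intervals.
#'
#' @inheritParams grid_search_svm
#' @param C,sigma hyperparameters of the fold models.
#' @return object of class `cv_result`: `folds` data frame (per-fold
#'   confusion counts and metrics), `summary` data frame (mean, ci_low,
#'   ci_high per metric), `fold_assignment`.
#' @export
kfold_cv <- function(x, labels, C, sigma, k_folds = 20, stratified = TRUE,
                     seed = 1L) {
  x <- as.matrix(x)
  y <- .encode_labels(labels)
  fold <- make_folds(y, k_folds, stratified, seed)
  K <- .rbf_matrix(x, x, sigma)
  rows <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    te <- which(fold == f)
    sc <- .cv_fold_scores(K, y, fold, f, C)
    pred <- ifelse(sc > 0, 1, -1)
    tp <- sum(pred == 1 & y[te] == 1); fn <- sum(pred == -1 & y[te] == 1)
    tn <- sum(pred == -1 & y[te] == -1); fp <- sum(pred == 1 & y[te] == -1)
    rows[[f]] <- data.frame(
      fold = f, n = length(te), TP = tp, FP = fp, TN = tn, FN = fn,
      sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
      accuracy = 100 * (tp + tn) / length(te))
  }
  folds <- do.call(rbind, rows)
  summarize <- function(v) {
    v <- v[!is.na(v)]
    se <- sd(v) / sqrt(length(v))
    c(mean = mean(v), ci_low = mean(v) - 1.96 * se,
      ci_high = mean(v) + 1.96 * se)
  }
  summary <- as.data.frame(t(vapply(
    folds[c("sensitivity", "specificity", "accuracy")], summarize,
    numeric(3))))
  summary$metric <- rownames(summary)
  structure(list(folds = folds, summary = summary,
                 fold_assignment = fold, C = C, sigma = sigma),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(nrow(x$folds), "fold cross-validation (C =", x$C, ", sigma =",
      signif(x$sigma, 4), ")\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
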