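#' SVM recursive feature elimination (RFE) ranking
#'
#' Iteratively retrains the RBF-kernel SVM on the surviving feature set,
#' scores every surviving feature by the drop-one kernel-weight criterion
#' (the change in the margin norm `||w||^2 = sum_ij alpha_i alpha_j y_i
#' y_j K_ij` when the feature is removed from the kernel), eliminates the
#' `step` least important features, and records the held-out sensitivity
#' of the surviving model after each round. The final survivor has rank 1;
#' features eliminated in the same round are ordered by their importance
#' at elimination.
#'
#' A constant feature changes no pairwise distance, so its criterion is
#' exactly zero and it is eliminated before any informative feature.
#'
#' @param x complete numeric training matrix (>= 2 features).
#' @param labels training class labels.
#' @param C,sigma SVM hyperparameters used in every round.
#' @param step features removed per round: an integer count, or a
#'   fraction in (0, 1) removing `max(1, floor(step * surviving))` per
#'   round. If `step` meets or exceeds the surviving set, the final round
#'   ranks the remainder.
#' @param x_test,labels_test held-out set for the per-round sensitivity
#'   trace; when omitted, a stratified 25% split of `x` is held out.
#' @param seed RNG seed for the internal split.
#' @return object of class `rfe_result`: `ranking` data frame (`feature`,
#'   `rank`, `round_eliminated`, rank 1 = last survivor) and `trace` data
#'   frame (`round`, `n_features`, `sensitivity`).
#' @export
rfe_rank <- function(x, labels, C = 1, sigma = NULL, step = 1,
                     x_test = NULL, labels_test = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) < 2) .fail("RFE needs at least 2 features")
  y <- .encode_labels(labels)
  if (is.null(x_test)) {
    set.seed(seed)
    hold <- unlist(lapply(c(-1, 1), function(cl) {
      idx <- which(y == cl)
      sample(idx, max(1L, floor(length(idx) / 4)))
    }))
    x_test <- x[hold, , drop = FALSE]
    y_test <- y[hold]
    x <- x[-hold, , drop = FALSE]
    y <- y[-hold]
  } else {
    y_test <- .encode_labels(labels_test)
  }
  if (is.null(sigma)) sigma <- .sigma_heuristic(x)

  feats <- colnames(x)
  if (is.null(feats)) feats <- sprintf("f%04d", seq_len(ncol(x)))
  surviving <- seq_len(ncol(x))
  ranking <- data.frame(feature = feats, rank = NA_integer_,
                        round_eliminated = NA_integer_,
                        stringsAsFactors = FALSE)
  trace <- list()
  next_rank <- ncol(x)  # worst rank assigned first
  round <- 0L
  repeat {
    round <- round + 1L
    xs <- x[, surviving, drop = FALSE]
    fit <- svm_rbf(xs, y, C = C, sigma = sigma, tol = 1e-3)
    sc <- decision_score(fit, x_test[, surviving, drop = FALSE])
    pos <- y_test == 1
    sens <- 100 * sum(sc[pos] > 0) / sum(pos)
    trace[[round]] <- data.frame(round = round,
                                 n_features = length(surviving),
                                 sensitivity = sens)

    ay <- fit$alpha * fit$y
    Ksv <- .rbf_matrix(fit$sv, fit$sv, sigma)
    B <- outer(ay, ay) * Ksv
    w2 <- sum(B)
    inv2s2 <- 1 / (2 * sigma^2)
    imp <- vapply(seq_along(surviving), function(fi) {
      d <- outer(fit$sv[, fi], fit$sv[, fi], "-")^2
      abs(sum(B * exp(d * inv2s2)) - w2)
    }, numeric(1))

    n_drop <- if (step > 0 && step < 1) {
      max(1L, floor(step * length(surviving)))
    } else as.integer(step)
    ord <- order(imp, feats[surviving])  # least important first
    if (n_drop >= length(surviving) || length(surviving) <= 1L) {
      # final round: rank the remainder by importance
      for (i in ord) {
        ranking$rank[surviving[i]] <- next_rank
        ranking$round_eliminated[surviving[i]] <- round
        next_rank <- next_rank - 1L
      }
      break
    }
    drop_i <- ord[seq_len(n_drop)]
    for (i in drop_i) {
      ranking$rank[surviving[i]] <- next_rank
      ranking$round_eliminated[surviving[i]] <- round
      next_rank <- next_rank - 1L
    }
    surviving <- surviving[-drop_i]
  }
  structure(list(ranking = ranking[order(ranking$rank), ],
                 trace = do.call(rbind, trace), C = C, sigma = sigma),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat("rfe_result:", nrow(x$ranking), "features ranked over",
      nrow(x$trace), "rounds\n")
  cat("top 5:", paste(x$ranking$feature[1:min(5, nrow(x$ranking))],
                      collapse = ", "), "\n")
  invisible(x)
}
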