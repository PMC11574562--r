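#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(low, high)` on the proportion scale.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Area under the ROC curve by rank statistics
#'
#' Mann-Whitney construction with tie correction: the AUC is the fraction
#' of (positive, negative) pairs in which the positive scores higher, with
#' half credit for ties.
#'
#' @param score numeric y-scores.
#' @param positive logical (or 0/1) indicator of the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) .fail("AUC needs both classes")
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix evaluation with subgroup sensitivities
#'
#' Applies the score cutoff (strictly above calls cancer), tabulates the
#' confusion counts, and computes sensitivity `100 * TP / (TP + FN)`,
#' specificity `100 * TN / (TN + FP)`, accuracy
#' `100 * (TP + TN) / total`, and the rank-based AUC. When sample
#' metadata is supplied, per-group detection sensitivities among the
#' cancer samples are reported for cancer type, stage, and age group,
#' each with a 95% Wilson score interval.
#'
#' @param score numeric y-scores.
#' @param labels `"cancer"`/`"normal"` labels aligned with `score`.
#' @param metadata optional data frame aligned with `score` providing
#'   `cancer_type`, `stage`, `age_group` columns.
#' @param cutoff decision threshold (default 0).
#' @param sample_id optional sample ids for the score table.
#' @return object of class `evaluation_report`: confusion counts,
#'   `sensitivity`/`specificity`/`accuracy` (percent), `auc`, `per_group`
#'   (data frame with `group_key`, `group`, `n_detected`, `n_total`,
#'   `sensitivity`, `ci_low`, `ci_high`), and `score_table`.
#' @export
evaluate_scores <- function(score, labels, metadata = NULL, cutoff = 0,
                            sample_id = NULL) {
  if (length(score) != length(labels)) {
    .fail("scores and labels differ in length")
  }
  labels <- ifelse(.encode_labels(labels) > 0, "cancer", "normal")
  pred <- classify_scores(score, cutoff)
  tp <- sum(pred == "cancer" & labels == "cancer")
  fn <- sum(pred == "normal" & labels == "cancer")
  tn <- sum(pred == "normal" & labels == "normal")
  fp <- sum(pred == "cancer" & labels == "normal")

  per_group <- NULL
  if (!is.null(metadata)) {
    if (nrow(metadata) != length(score)) {
      .fail("metadata is not aligned with the scores")
    }
    rows <- list()
    for (key in intersect(c("cancer_type", "stage", "age_group"),
                          names(metadata))) {
      canc <- labels == "cancer"
      for (g in sort(unique(metadata[[key]][canc]))) {
        idx <- canc & metadata[[key]] == g
        k <- sum(pred[idx] == "cancer"); n <- sum(idx)
        ci <- wilson_ci(k, n)
        rows[[length(rows) + 1L]] <- data.frame(
          group_key = key, group = g, n_detected = k, n_total = n,
          sensitivity = 100 * k / n, ci_low = 100 * ci[1],
          ci_high = 100 * ci[2], stringsAsFactors = FALSE)
      }
    }
    per_group <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  if (is.null(sample_id)) sample_id <- sprintf("s%04d", seq_along(score))
  structure(list(
    TP = tp, FP = fp, TN = tn, FN = fn,
    sensitivity = 100 * tp / max(tp + fn, 1L),
    specificity = 100 * tn / max(tn + fp, 1L),
    accuracy = 100 * (tp + tn) / length(score),
    auc = if (tp + fn > 0 && tn + fp > 0) {
      auc_rank(score, labels == "cancer")
    } else NA_real_,
    cutoff = cutoff, per_group = per_group,
    score_table = data.frame(sample_id = sample_id, y_score = score,
                             label = labels, predicted = pred,
                             stringsAsFactors = FALSE)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report: n = %d (TP %d, FN %d, TN %d, FP %d)\n",
    nrow(x$score_table), x$TP, x$FN, x$TN, x$FP))
  cat(sprintf(
    "  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%  AUC %.3f\n",
    x$sensitivity, x$specificity, x$accuracy, x$auc))
  if (!is.null(x$per_group)) {
    cat("  subgroup sensitivities over",
        length(unique(x$per_group$group_key)), "group keys (see $per_group)\n")
  }
  invisible(x)
}

#' Write an evaluation report as JSON plus a per-sample score CSV
#'
#' @param report an `evaluation_report`.
#' @param path JSON path; the score table is written next to it as
#'   `<path>.scores.csv` with columns `sample_id,y_score,label,predicted`.
#' @return invisibly, `path`.
#' @export
write_evaluation_report <- function(report, path) {
  out <- unclass(report)
  out$score_table <- NULL
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  write.csv(report$score_table, paste0(path, ".scores.csv"),
            row.names = FALSE)
  invisible(path)
}
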