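#' Fit the multi-cancer detection model on an annotated feature matrix
#'
#' The central fitting routine. Starting from a raw (intensity-scale)
#' annotated [feature_matrix()], it applies the training workflow in
#' order: curation filter (human-origin metabolites only), prevalence or
#' abundance feature reduction, log10 scaling, train-referenced quantile
#' normalization, chained-equations imputation, hyperparameter grid
#' search with stratified k-fold cross-validation, and a final RBF-kernel
#' SVM on the full training set. All per-sample steps (normalization,
#' imputation, scoring) use frozen train-time artifacts, so a fitted
#' model can process one test sample at a time.
#'
#' @param fm raw annotated training [feature_matrix()].
#' @param metadata training metadata aligned by `sample_id` (needs a
#'   `class` column of `"cancer"`/`"normal"`).
#' @param library the `metabolite_library` used for annotation.
#' @param filter_mode `"prevalence"` (default) or `"abundance_percentile"`
#'   passed to [filter_features()].
#' @param min_presence_fraction,k_percent filter parameters.
#' @param c_grid,sigma_grid hyperparameter grids for [grid_search_svm()].
#' @param k_folds cross-validation folds (default 20).
#' @param mice_iterations maximum imputation iterations (default 5).
#' @param regressor imputation regressor backend ([xgb_regressor()]).
#' @param seed integer seed controlling folds and imputation.
#' @return object of class `mcd_model`: frozen preprocessing artifacts
#'   (`kept_features`, `norm_ref`, `mice`), the fitted `svm`, selected
#'   `C`/`sigma`, the grid-search `cv_table`, the k-fold `cv` result, and
#'   `train_sample_ids`.
#' @seealso [predict.mcd_model()], [run_train()], [run_validate()]
#' @export
mcd_fit <- function(fm, metadata, library,
                    filter_mode = c("prevalence", "abundance_percentile"),
                    min_presence_fraction = 0.2, k_percent = 20,
                    c_grid = c(0.1, 1, 10, 100), sigma_grid = NULL,
                    k_folds = 20, mice_iterations = 5,
                    regressor = xgb_regressor(), seed = 1L) {
  filter_mode <- match.arg(filter_mode)
  ids <- rownames(fm$values)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$class)) .fail("metadata is missing some training samples")
  labels <- meta$class

  fm1 <- filter_nonhuman(fm, library)
  fm1 <- filter_features(fm1, mode = filter_mode,
                         min_presence_fraction = min_presence_fraction,
                         k_percent = k_percent)
  fm1 <- log_transform(fm1)
  norm_ref <- fit_quantile_reference(fm1)
  fm1 <- normalize_quantiles(fm1, norm_ref)
  mice <- fit_mice(fm1, max_iterations = mice_iterations, seed = seed,
                   regressor = regressor)
  xtr <- mice$completed$values

  gs <- grid_search_svm(xtr, labels, c_grid = c_grid,
                        sigma_grid = sigma_grid, k_folds = k_folds,
                        seed = seed)
  cv <- kfold_cv(xtr, labels, C = gs$best_C, sigma = gs$best_sigma,
                 k_folds = k_folds, seed = seed)
  svm <- svm_rbf(xtr, labels, C = gs$best_C, sigma = gs$best_sigma)

  structure(list(
    kept_features = mice$completed$features,
    norm_ref = norm_ref, mice = mice$model, svm = svm,
    C = gs$best_C, sigma = gs$best_sigma, cv_table = gs$cv_table,
    cv = cv, train_matrix = mice$completed,
    train_sample_ids = ids, filter_mode = filter_mode,
    min_presence_fraction = min_presence_fraction,
    k_percent = k_percent, k_folds = k_folds, seed = seed),
    class = "mcd_model")
}

#' @export
print.mcd_model <- function(x, ...) {
  cat("Multi-cancer detection model\n")
  cat("  training samples:", length(x$train_sample_ids),
      " retained features:", nrow(x$kept_features), "\n")
  cat("  SVM-RBF: C =", x$C, ", sigma =", signif(x$sigma, 4), ",",
      length(x$svm$alpha), "support vectors\n")
  s <- x$cv$summary
  cat(sprintf("  %d-fold CV: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              x$k_folds, s$mean[s$metric == "sensitivity"],
              s$mean[s$metric == "specificity"],
              s$mean[s$metric == "accuracy"]))
  invisible(x)
}

#' @export
summary.mcd_model <- function(object, ...) {
  cat("Preprocessing:\n  ")
  cat(paste(object$train_matrix$transform_log, collapse = "\n  "), "\n")
  print(object)
  cat("Cross-validation summary:\n")
  print(object$cv$summary, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
plot.mcd_model <- function(x, ...) {
  f <- x$cv$folds
  graphics::plot(f$fold, f$sensitivity, type = "b", pch = 19,
                 xlab = "fold", ylab = "sensitivity (%)",
                 ylim = c(0, 100),
                 main = sprintf("%d-fold CV sensitivity", nrow(f)), ...)
  graphics::abline(h = mean(f$sensitivity, na.rm = TRUE), lty = 2,
                   col = "blue")
  invisible(x)
}

# map a raw test feature matrix onto the model's retained feature space;
# features absent from the test matrix become missing
.project_features <- function(fm, model) {
  ids <- model$kept_features$metabolite_id
  idx <- match(ids, fm$features$metabolite_id)
  vals <- matrix(NA_real_, nrow(fm$values), length(ids),
                 dimnames = list(rownames(fm$values), ids))
  got <- !is.na(idx)
  vals[, got] <- fm$values[, idx[got], drop = FALSE]
  vals
}

#' Score new samples with a fitted multi-cancer detection model
#'
#' Each sample is processed independently through the frozen train-time
#' artifacts: log10 scaling, single-sample quantile normalization against
#' the training reference, frozen-regressor imputation, and the SVM
#' decision function. Processing a matrix row-by-row therefore gives the
#' same result as processing it at once.
#'
#' @param object a fitted `mcd_model`.
#' @param newdata a raw annotated [feature_matrix()] (intensity scale), or
#'   a single sample as a named numeric vector of intensities.
#' @param type `"score"` (y-scores), `"class"` (cancer/normal calls), or
#'   `"report"` (an [evaluate_scores()] report; requires `labels`).
#' @param labels,metadata used when `type = "report"`.
#' @param cutoff decision threshold (default 0).
#' @param ... ignored.
#' @return numeric scores, character classes, or an `evaluation_report`.
#' @export
predict.mcd_model <- function(object, newdata,
                              type = c("score", "class", "report"),
                              labels = NULL, metadata = NULL, cutoff = 0,
                              ...) {
  type <- match.arg(type)
  single <- is.numeric(newdata) && is.null(dim(newdata))
  if (single) {
    ids <- object$kept_features$metabolite_id
    v <- stats::setNames(rep(NA_real_, length(ids)), ids)
    got <- intersect(names(newdata), ids)
    v[got] <- newdata[got]
    vals <- matrix(v, 1, dimnames = list("sample", ids))
  } else {
    vals <- .project_features(newdata, object)
  }
  scores <- numeric(nrow(vals))
  for (s in seq_len(nrow(vals))) {
    v <- vals[s, ]
    if (any(v <= 0, na.rm = TRUE)) {
      .fail("observed intensities must be positive")
    }
    v <- log10(v)
    v <- normalize_quantiles(v, object$norm_ref)
    v <- impute(v, object$mice)
    scores[s] <- decision_score(object$svm, v)
  }
  names(scores) <- rownames(vals)
  switch(type,
         score = scores,
         class = classify_scores(scores, cutoff),
         report = evaluate_scores(scores, labels, metadata,
                                  cutoff = cutoff,
                                  sample_id = rownames(vals)))
}

#' Stratified train/validation split of a cohort
#'
#' Splits samples by class (and cancer type within the cancer class) into
#' a training-testing set and a held-out validation set. Default
#' fractions follow the study design template (about 51% of cancers and
#' 50% of controls in the training-testing set); exact per-set counts can
#' be requested instead.
#'
#' @param metadata cohort metadata with `sample_id`, `class`,
#'   `cancer_type`.
#' @param train_cancer,train_normal either fractions in (0, 1) or exact
#'   integer counts of cancer/normal samples to place in the
#'   training-testing set.
#' @param seed RNG seed.
#' @return list with character vectors `train_ids` and `validate_ids`.
#' @export
split_cohort <- function(metadata,
                         train_cancer = 1445 / 2831,
                         train_normal = 1812 / 3614, seed = 1L) {
  set.seed(seed)
  pick <- function(ids, want) {
    n <- length(ids)
    k <- if (want < 1) round(want * n) else min(as.integer(want), n)
    sample(ids, k)
  }
  train <- character(0)
  canc <- metadata[metadata$class == "cancer", , drop = FALSE]
  if (nrow(canc)) {
    if (train_cancer < 1) {
      # stratify the fractional split by cancer type
      for (t in unique(canc$cancer_type)) {
        ids <- canc$sample_id[canc$cancer_type == t]
        train <- c(train, pick(ids, train_cancer))
      }
    } else {
      train <- c(train, pick(canc$sample_id, train_cancer))
    }
  }
  norm_ids <- metadata$sample_id[metadata$class == "normal"]
  if (length(norm_ids)) train <- c(train, pick(norm_ids, train_normal))
  list(train_ids = sort(train),
       validate_ids = sort(setdiff(metadata$sample_id, train)))
}

#' Run the end-to-end training workflow
#'
#' Orchestrates the full pipeline on a (simulated) cohort: cohort
#' generation, train/validation split, VLM anchor detection on the
#' training runs, per-run mass correction, feature-matrix assembly and
#' annotation, and [mcd_fit()]. Artifacts (normalization reference, SVM
#' bundle, cross-validation report, metadata) are archived under
#' `out_dir` with recorded MD5 hashes so a run can be audited and
#' replayed.
#'
#' @param config a [cohort_config()]; the cohort and library are
#'   simulated from it unless supplied.
#' @param out_dir artifact directory (default a fresh temporary
#'   directory).
#' @param cohort optionally, a pre-built `mcd_cohort`.
#' @param library optionally, a pre-built `metabolite_library`.
#' @param anchor_ppm_window anchor window passed to
#'   [detect_vlm_anchors()]; the default spans the configured drift range.
#' @param min_presence anchor presence threshold (default 0.9).
#' @param annotation_ppm,rt_tolerance annotation tolerances.
#' @param train_cancer,train_normal split fractions or counts, see
#'   [split_cohort()].
#' @param ... further arguments to [mcd_fit()].
#' @return object of class `run_manifest`: the fitted `model`, the
#'   held-out cohort pieces, per-stage timings, artifact paths and
#'   hashes.
#' @export
run_train <- function(config, out_dir = tempfile("mcd_run_"),
                      cohort = NULL, library = NULL,
                      anchor_ppm_window = NULL, min_presence = 0.9,
                      annotation_ppm = 10, rt_tolerance = 30,
                      train_cancer = 1445 / 2831,
                      train_normal = 1812 / 3614, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0, stage) {
    timings[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
  }

  t0 <- tic()
  if (is.null(library)) {
    library <- simulate_library(config$n_metabolites, seed = config$seed)
  }
  if (is.null(cohort)) cohort <- simulate_cohort(config, library)
  lap(t0, "simulate")

  split <- split_cohort(cohort$metadata, train_cancer, train_normal,
                        seed = config$seed)
  run_ids <- vapply(cohort$runs, `[[`, character(1), "run_id")
  train_runs <- cohort$runs[run_ids %in% split$train_ids]

  t0 <- tic()
  if (is.null(anchor_ppm_window)) {
    anchor_ppm_window <- max(10, 1.5 * max(abs(config$drift_ppm_range)))
  }
  anchors <- detect_vlm_anchors(train_runs, ppm_window = anchor_ppm_window,
                                min_presence = min_presence)
  corrected <- lapply(train_runs, correct_masses, anchors = anchors)
  fm <- build_feature_matrix(corrected, library,
                             annotation_ppm = annotation_ppm,
                             rt_tolerance = rt_tolerance)
  lap(t0, "align")

  t0 <- tic()
  model <- mcd_fit(fm, cohort$metadata, library, seed = config$seed, ...)
  lap(t0, "fit")

  # archive the frozen artifacts
  paths <- c(
    norm_ref = file.path(out_dir, "normalization_reference.json"),
    metadata = file.path(out_dir, "metadata.csv"),
    cv_report = file.path(out_dir, "cv_report.json"))
  write_normalization_reference(model$norm_ref, paths[["norm_ref"]])
  write.csv(cohort$metadata, paths[["metadata"]], row.names = FALSE)
  jsonlite::write_json(list(cv_table = model$cv_table,
                            folds = model$cv$folds,
                            summary = model$cv$summary),
                       paths[["cv_report"]], digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  write_svm_model(model$svm, file.path(out_dir, "svm_model"))
  paths[["svm_manifest"]] <- file.path(out_dir, "svm_model",
                                       "manifest.json")
  paths[["svm_sv"]] <- file.path(out_dir, "svm_model",
                                 "support_vectors.csv")
  hashes <- tools::md5sum(paths)

  structure(list(
    config = config, seed = config$seed, model = model,
    anchors = anchors, library = library, cohort = cohort,
    split = split, out_dir = out_dir,
    artifacts = data.frame(stage = names(paths), path = unname(paths),
                           md5 = unname(hashes),
                           stringsAsFactors = FALSE),
    timings = timings,
    version = as.character(utils::packageVersion("metabodetect"))),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", length(x$split$train_ids), "training /",
      length(x$split$validate_ids), "validation samples\n")
  cat("  artifacts in", x$out_dir, "\n")
  print(x$model)
  invisible(x)
}

#' Validate a trained model on held-out samples
#'
#' Feeds held-out runs one sample at a time through the frozen train-time
#' artifacts (anchor set, normalization reference, imputation model, SVM)
#' and evaluates the resulting y-scores with subgroup breakdowns. A
#' sample-id audit refuses any overlap between training and validation
#' samples.
#'
#' @param manifest a `run_manifest` from [run_train()].
#' @param runs validation `peak_list`s; default the manifest's held-out
#'   split.
#' @param metadata metadata for the validation samples.
#' @return an [evaluate_scores()] report.
#' @export
run_validate <- function(manifest, runs = NULL, metadata = NULL) {
  if (is.null(runs)) {
    run_ids <- vapply(manifest$cohort$runs, `[[`, character(1), "run_id")
    runs <- manifest$cohort$runs[run_ids %in% manifest$split$validate_ids]
    metadata <- manifest$cohort$metadata
  }
  ids <- vapply(runs, `[[`, character(1), "run_id")
  overlap <- intersect(ids, manifest$model$train_sample_ids)
  if (length(overlap)) {
    .fail("leakage audit failed: validation sample(s) were used in ",
          "training: ", paste(utils::head(overlap, 5), collapse = ", "))
  }
  corrected <- lapply(runs, correct_masses, anchors = manifest$anchors)
  fm <- build_feature_matrix(corrected, manifest$library)
  scores <- predict(manifest$model, fm)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  evaluate_scores(scores, meta$class, metadata = meta, sample_id = ids)
}
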