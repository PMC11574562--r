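#' Feature matrix container
#'
#' Samples-by-features intensity matrix with feature annotations and an
#' append-only transform log recording the preprocessing provenance.
#' Missing measurements are `NA` (a peak that was never observed), never
#' zero.
#'
#' @param values numeric matrix, rows = samples (rownames = sample ids),
#'   columns = annotated metabolite features.
#' @param features data frame with one row per column of `values`:
#'   `metabolite_id`, `consensus_mz`, `consensus_rt`.
#' @param transform_log character vector of applied transforms.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, features,
                           transform_log = character()) {
  stopifnot(is.matrix(values), nrow(features) == ncol(values),
            identical(colnames(values), features$metabolite_id))
  structure(list(values = values, features = features,
                 transform_log = transform_log),
            class = "feature_matrix")
}

# append a provenance entry
.log_transform <- function(fm, entry) {
  fm$transform_log <- c(fm$transform_log, entry)
  fm
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "features;", round(100 * mean(is.na(x$values)), 1), "% missing\n")
  if (length(x$transform_log)) {
    cat("transforms:", paste(x$transform_log, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Subset a feature matrix
#'
#' @param x a `feature_matrix`.
#' @param i sample index (rows); @param j feature index (columns).
#' @param ... ignored.
#' @return a `feature_matrix` restricted to the requested samples/features.
#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  feature_matrix(x$values[i, j, drop = FALSE],
                 x$features[j, , drop = FALSE],
                 x$transform_log)
}

#' Write / read a feature matrix as CSV plus a JSON annotation sidecar
#'
#' The CSV holds samples as rows (first column `sample_id`) and metabolite
#' ids as columns; the sidecar JSON carries feature annotations and the
#' transform log.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.annotations.json`.
#' @return `read_feature_matrix()` returns the `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(sample_id = rownames(fm$values), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  side <- list(features = fm$features, transform_log = fm$transform_log)
  jsonlite::write_json(side, paste0(path, ".annotations.json"),
                       dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  side <- jsonlite::read_json(paste0(path, ".annotations.json"),
                              simplifyVector = TRUE)
  feature_matrix(values, as.data.frame(side$features),
                 as.character(side$transform_log))
}
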