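#' Remove features of non-human origin
#'
#' Curation filter: drops every feature whose library record is flagged
#' `drug`, `plant`, or `ambiguous`, retaining exactly the metabolites of
#' unambiguous human origin. The sample set is unchanged.
#'
#' @param fm a [feature_matrix()].
#' @param library the `metabolite_library` the matrix was annotated
#'   against; every matrix feature must exist in it.
#' @return the filtered `feature_matrix` (provenance appended).
#' @export
filter_nonhuman <- function(fm, library) {
  idx <- match(fm$features$metabolite_id, library$metabolite_id)
  if (anyNA(idx)) {
    .fail("feature(s) missing from library: ",
          paste(fm$features$metabolite_id[is.na(idx)], collapse = ", "))
  }
  keep <- which(library$origin[idx] == "human")
  if (length(keep) == 0) .fail("curation filter removed every feature")
  out <- fm[, keep]
  .log_transform(out, sprintf("filter_nonhuman(kept=%d)", length(keep)))
}

#' Prevalence / abundance feature filter
#'
#' Two data-adaptive feature-reduction modes. `prevalence` keeps features
#' observed (non-missing) in at least `min_presence_fraction` of samples
#' (boundary inclusive). `abundance_percentile` ranks features by mean
#' observed log10 intensity and drops the lowest `k_percent` percent
#' (`floor(k_percent/100 * n_features)` features; ties broken by
#' metabolite id).
#'
#' @param fm a [feature_matrix()].
#' @param mode `"prevalence"` (default) or `"abundance_percentile"`.
#' @param min_presence_fraction presence threshold in `[0, 1]`
#'   (default 0.20).
#' @param k_percent percentage of lowest-abundance features to drop in
#'   `abundance_percentile` mode (default 20).
#' @return the filtered `feature_matrix` (provenance appended).
#' @export
filter_features <- function(fm, mode = c("prevalence",
                                         "abundance_percentile"),
                            min_presence_fraction = 0.20, k_percent = 20) {
  mode <- match.arg(mode)
  if (ncol(fm$values) == 0) .fail("feature matrix is empty")
  if (k_percent < 0 || k_percent >= 100) .fail("`k_percent` outside [0,100)")
  if (mode == "prevalence") {
    presence <- colMeans(!is.na(fm$values))
    keep <- which(presence >= min_presence_fraction)
    entry <- sprintf("filter_prevalence(min=%g,kept=%d)",
                     min_presence_fraction, length(keep))
  } else {
    vals <- fm$values
    if (!"log10" %in% fm$transform_log) vals <- log10(vals)
    mean_ab <- colMeans(vals, na.rm = TRUE)
    n_drop <- floor(k_percent / 100 * ncol(vals))
    ord <- order(mean_ab, fm$features$metabolite_id)
    keep <- sort(setdiff(seq_len(ncol(vals)),
                         ord[seq_len(n_drop)]))
    entry <- sprintf("filter_abundance(k=%g%%,kept=%d)", k_percent,
                     length(keep))
  }
  if (length(keep) == 0) .fail("feature filter removed every feature")
  .log_transform(fm[, keep], entry)
}

#' Log10-scale observed intensities
#'
#' Replaces every observed cell by its base-10 logarithm; missing cells
#' stay missing. Double application is refused via the transform log.
#'
#' @param fm a [feature_matrix()] of raw (positive) intensities.
#' @return the log-scaled `feature_matrix`.
#' @export
log_transform <- function(fm) {
  if ("log10" %in% fm$transform_log) {
    .fail("matrix is already log10-scaled (provenance check)")
  }
  obs <- fm$values[!is.na(fm$values)]
  if (any(obs <= 0)) .fail("log10 requires all observed intensities > 0")
  fm$values <- log10(fm$values)
  .log_transform(fm, "log10")
}

#' Fit a train-set quantile-normalization reference
#'
#' Computes the reference distribution for single-sample quantile
#' normalization: each training sample's sorted observed values are
#' linearly interpolated onto a common grid of `n_features` probability
#' points `(r - 0.5) / n_features`, and the reference is the mean across
#' samples at each grid point. On complete data this reduces to textbook
#' quantile normalization (mean of r-th order statistics); with unequal
#' missingness the interpolation keeps the grids commensurate.
#'
#' @param fm a log-scaled training [feature_matrix()] with >= 2 samples;
#'   every sample needs >= 2 observed values.
#' @return object of class `normalization_reference`: sorted
#'   `reference_quantiles` (length = number of features), `feature_order`
#'   (metabolite ids), `provenance`.
#' @export
fit_quantile_reference <- function(fm) {
  if (!"log10" %in% fm$transform_log) {
    .fail("quantile reference must be fit on log10-scaled data")
  }
  x <- fm$values
  if (nrow(x) < 2) .fail("need >= 2 training samples")
  p <- ncol(x)
  grid <- (seq_len(p) - 0.5) / p
  acc <- numeric(p)
  for (s in seq_len(nrow(x))) {
    v <- sort(x[s, !is.na(x[s, ])])
    m <- length(v)
    if (m < 2) .fail("sample ", rownames(x)[s], " has < 2 observed values")
    acc <- acc + approx((seq_len(m) - 0.5) / m, v, xout = grid,
                        rule = 2)$y
  }
  structure(list(reference_quantiles = acc / nrow(x),
                 feature_order = fm$features$metabolite_id,
                 provenance = sprintf("train[%dx%d]", nrow(x), p)),
            class = "normalization_reference")
}

#' @export
print.normalization_reference <- function(x, ...) {
  cat("normalization_reference:", length(x$reference_quantiles),
      "quantiles from", x$provenance, "\n")
  invisible(x)
}

# normalize one numeric vector (NA = missing) against a reference
.normalize_vector <- function(v, ref) {
  obs <- which(!is.na(v))
  m <- length(obs)
  if (m == 0) return(v)
  p <- length(ref)
  grid <- (seq_len(p) - 0.5) / p
  # reference value at each within-sample rank position
  q_at_rank <- approx(grid, ref, xout = (seq_len(m) - 0.5) / m,
                      rule = 2)$y
  r <- rank(v[obs], ties.method = "average")
  # tied values share the mean of the reference values their ranks span
  out <- numeric(m)
  ties <- duplicated(r) | duplicated(r, fromLast = TRUE)
  out[!ties] <- q_at_rank[r[!ties]]
  if (any(ties)) {
    rmin <- rank(v[obs], ties.method = "min")
    rmax <- rank(v[obs], ties.method = "max")
    for (i in which(ties)) {
      out[i] <- mean(q_at_rank[rmin[i]:rmax[i]])
    }
  }
  v[obs] <- out
  v
}

#' Apply single-sample quantile normalization
#'
#' Maps each sample's observed values onto the training reference
#' distribution independently of every other sample: the r-th smallest of
#' m observed values is assigned the reference quantile at grid position
#' `(r - 0.5) / m` (linear interpolation); tied values receive the mean of
#' the reference values their ranks span; missing cells stay missing.
#' Because samples are processed independently, normalizing a matrix
#' row-by-row equals normalizing it at once, which is what makes the
#' procedure usable on a single test sample at a time.
#'
#' @param fm a log-scaled [feature_matrix()] (or a single sample as a
#'   named numeric vector in reference feature order).
#' @param ref a `normalization_reference` from [fit_quantile_reference()];
#'   feature order must match.
#' @return the normalized object (same shape as the input).
#' @export
normalize_quantiles <- function(fm, ref) {
  if (is.numeric(fm) && is.null(dim(fm))) {
    if (length(fm) != length(ref$feature_order)) {
      .fail("sample length does not match reference feature order")
    }
    return(.normalize_vector(fm, ref$reference_quantiles))
  }
  if (!identical(fm$features$metabolite_id, ref$feature_order)) {
    .fail("feature order does not match the normalization reference")
  }
  for (s in seq_len(nrow(fm$values))) {
    fm$values[s, ] <- .normalize_vector(fm$values[s, ],
                                        ref$reference_quantiles)
  }
  .log_transform(fm, "quantile_normalized")
}

#' Serialize / load a normalization reference as JSON
#'
#' @param ref a `normalization_reference`.
#' @param path JSON file path.
#' @return `read_normalization_reference()` returns the reference.
#' @export
write_normalization_reference <- function(ref, path) {
  jsonlite::write_json(unclass(ref), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_normalization_reference
#' @export
read_normalization_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(reference_quantiles = as.numeric(x$reference_quantiles),
                 feature_order = as.character(x$feature_order),
                 provenance = x$provenance),
            class = "normalization_reference")
}
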