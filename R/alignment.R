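#' Detect virtual-lock-mass (VLM) anchors across runs
#'
#' Mass-spectrometer calibration drifts between runs, shifting every m/z by
#' a run-specific relative (ppm) error. Peaks that are reliably present in
#' nearly all runs can act as internal anchors: their cross-run consensus
#' m/z estimates the true mass, and each run's deviation from consensus
#' estimates that run's mass error. An anchor is accepted when every
#' matched run contributes exactly one peak within `ppm_window` of the
#' consensus (ambiguous windows are discarded) and the fraction of matched
#' runs is at least `min_presence`.
#'
#' `ppm_window` must be wide enough to span the drift range in play: with
#' per-run drift up to +/-30 ppm, a window of about 40 ppm is needed for
#' one metabolite's peaks to fall in a single window across runs.
#'
#' @param runs list of `peak_list` objects (>= 2).
#' @param ppm_window half-width of the anchor window, ppm (default 10).
#' @param min_presence minimum fraction of runs an anchor must match
#'   (default 0.95).
#' @return object of class `vlm_anchor_set`: `anchors` (data frame with
#'   `consensus_mz` and per-run match counts), `run_error` (runs x anchors
#'   matrix of observed ppm error, `NA` where unmatched), `run_ids`,
#'   `ppm_window`, `min_presence`.
#' @export
detect_vlm_anchors <- function(runs, ppm_window = 10, min_presence = 0.95) {
  if (length(runs) < 2) .fail("anchor detection needs at least 2 runs")
  if (ppm_window <= 0) .fail("`ppm_window` must be positive")
  if (min_presence <= 0 || min_presence > 1) {
    .fail("`min_presence` must lie in (0, 1]")
  }
  n_runs <- length(runs)
  run_ids <- vapply(runs, function(r) r$run_id, character(1))

  mz <- unlist(lapply(runs, function(r) r$peaks$mz), use.names = FALSE)
  run_of <- rep.int(seq_len(n_runs),
                    vapply(runs, function(r) nrow(r$peaks), integer(1)))
  ord <- order(mz)
  mz <- mz[ord]; run_of <- run_of[ord]

  # cluster pooled peaks: break where the relative gap exceeds the window
  gap <- diff(mz) / mz[-length(mz)] * 1e6
  cluster <- cumsum(c(1L, gap > ppm_window))

  consensus <- vapply(split(mz, cluster), mean, numeric(1))
  n_in <- tabulate(cluster)
  keep <- which(n_in >= ceiling(min_presence * n_runs))

  anchors_mz <- numeric(0)
  err_rows <- list()
  cl_mz <- split(mz, cluster)
  cl_run <- split(run_of, cluster)
  for (k in keep) {
    cmz <- consensus[k]
    ppm <- (cl_mz[[k]] - cmz) / cmz * 1e6
    inw <- abs(ppm) <= ppm_window
    if (!any(inw)) next
    r_in <- cl_run[[k]][inw]
    if (anyDuplicated(r_in)) next                    # ambiguous window
    if (length(r_in) < min_presence * n_runs) next   # presence threshold
    cons <- mean(cl_mz[[k]][inw])                    # consensus of matches
    e <- rep(NA_real_, n_runs)
    e[r_in] <- (cl_mz[[k]][inw] - cons) / cons * 1e6
    anchors_mz <- c(anchors_mz, cons)
    err_rows[[length(err_rows) + 1L]] <- e
  }
  run_error <- if (length(err_rows)) {
    t(matrix(unlist(err_rows), nrow = n_runs))
  } else matrix(numeric(0), 0, n_runs)
  # recompute error against the final consensus (mean of matched peaks)
  if (length(anchors_mz)) {
    ord_a <- order(anchors_mz)
    anchors_mz <- anchors_mz[ord_a]
    run_error <- run_error[ord_a, , drop = FALSE]
  }
  structure(list(
    anchors = data.frame(consensus_mz = anchors_mz,
                         n_matched = rowSums(!is.na(run_error))),
    run_error = t(run_error),  # runs x anchors
    run_ids = run_ids, ppm_window = ppm_window,
    min_presence = min_presence), class = "vlm_anchor_set")
}

#' @export
print.vlm_anchor_set <- function(x, ...) {
  cat("VLM anchor set:", nrow(x$anchors), "anchors over",
      length(x$run_ids), "runs (window +/-", x$ppm_window, "ppm)\n")
  invisible(x)
}

# per-run ppm error profile against an anchor set, matching the run's
# peaks to anchor windows (exactly one peak per window, else NA)
.run_anchor_errors <- function(run, anchors) {
  idx <- match(run$run_id, anchors$run_ids)
  if (!is.na(idx)) return(anchors$run_error[idx, ])
  cmz <- anchors$anchors$consensus_mz
  mz <- sort(run$peaks$mz)
  e <- rep(NA_real_, length(cmz))
  for (a in seq_along(cmz)) {
    w <- anchors$ppm_window * 1e-6 * cmz[a]
    lo <- findInterval(cmz[a] - w, mz)
    hi <- findInterval(cmz[a] + w, mz)
    if (hi - lo == 1L) e[a] <- (mz[hi] - cmz[a]) / cmz[a] * 1e6
  }
  e
}

#' Correct a run's m/z values using VLM anchors
#'
#' Divides each peak's m/z by `1 + e(mz)/1e6`, where `e(mz)` is the run's
#' ppm error piecewise-linearly interpolated between flanking anchors
#' (constant extrapolation beyond the first/last anchor). Retention times,
#' intensities and peak order are unchanged.
#'
#' @param run a `peak_list`.
#' @param anchors a `vlm_anchor_set`; the run may have contributed to the
#'   set or is matched against it by m/z.
#' @return the corrected `peak_list`. With an empty anchor set (or no
#'   matched anchors for this run) the run is returned unchanged with a
#'   warning.
#' @export
correct_masses <- function(run, anchors) {
  if (nrow(anchors$anchors) == 0) {
    warning("empty anchor set: returning run uncorrected")
    return(run)
  }
  e <- .run_anchor_errors(run, anchors)
  ok <- !is.na(e)
  if (!any(ok)) {
    warning("run matched no anchors: returning run uncorrected")
    return(run)
  }
  cmz <- anchors$anchors$consensus_mz[ok]
  ev <- e[ok]
  err_at <- if (length(ev) == 1L) {
    rep(ev, nrow(run$peaks))
  } else {
    approx(cmz, ev, xout = run$peaks$mz, rule = 2)$y
  }
  run$peaks$mz <- run$peaks$mz / (1 + err_at / 1e6)
  run
}

#' Assemble an annotated cross-run feature matrix
#'
#' Annotates each (corrected) peak to the library record minimizing the
#' absolute ppm difference between the observed m/z and the protonated
#' library mass, subject to the ppm difference being at most
#' `annotation_ppm` and the retention-time deviation from the library's
#' nominal RT at most `rt_tolerance`. Unannotated peaks are dropped. The
#' matrix has one column per annotated metabolite; if a run yields two
#' peaks for one metabolite, the higher-intensity peak wins; a sample with
#' no peak for a feature holds `NA`.
#'
#' @param runs list of corrected `peak_list` objects.
#' @param library a `metabolite_library`.
#' @param annotation_ppm ppm tolerance for annotation (default 10).
#' @param rt_tolerance retention-time tolerance in seconds (default 30).
#' @return a [feature_matrix()].
#' @export
build_feature_matrix <- function(runs, library, annotation_ppm = 10,
                                 rt_tolerance = 30) {
  if (length(runs) == 0) .fail("`runs` must be non-empty")
  if (annotation_ppm <= 0) .fail("`annotation_ppm` must be positive")
  lib_mz <- library$monoisotopic_mass + PROTON_MASS
  ord <- order(lib_mz)
  lib_mz_s <- lib_mz[ord]
  lib_rt_s <- library$nominal_rt[ord]

  n <- length(runs); p <- nrow(library)
  values <- matrix(NA_real_, n, p,
                   dimnames = list(vapply(runs, `[[`, character(1),
                                          "run_id"),
                                   library$metabolite_id))
  mz_sum <- rt_sum <- cnt <- numeric(p)
  for (s in seq_len(n)) {
    pk <- runs[[s]]$peaks
    if (nrow(pk) == 0) next
    i_hi <- findInterval(pk$mz, lib_mz_s)
    best <- integer(nrow(pk)); best_ppm <- numeric(nrow(pk))
    for (side in 0:1) {
      cand <- i_hi + side
      ok <- cand >= 1 & cand <= p
      ppm <- rep(Inf, nrow(pk))
      ppm[ok] <- abs(pk$mz[ok] - lib_mz_s[cand[ok]]) /
        lib_mz_s[cand[ok]] * 1e6
      upd <- if (side == 0) rep(TRUE, nrow(pk)) else ppm < best_ppm
      best[upd] <- cand[upd]; best_ppm[upd] <- ppm[upd]
    }
    keep <- best_ppm <= annotation_ppm & best >= 1 & best <= p
    keep[keep] <- abs(pk$rt[keep] - lib_rt_s[best[keep]]) <= rt_tolerance
    if (!any(keep)) next
    feat <- ord[best[keep]]                    # index into library order
    inten <- pk$intensity[keep]
    # duplicate annotations within a run: higher intensity wins
    o <- order(feat, -inten)
    first <- !duplicated(feat[o])
    f_idx <- feat[o][first]
    values[s, f_idx] <- inten[o][first]
    mz_sum[f_idx] <- mz_sum[f_idx] + pk$mz[keep][o][first]
    rt_sum[f_idx] <- rt_sum[f_idx] + pk$rt[keep][o][first]
    cnt[f_idx] <- cnt[f_idx] + 1
  }
  used <- which(cnt > 0)
  if (length(used) == 0) .fail("no peak could be annotated to the library")
  features <- data.frame(
    metabolite_id = library$metabolite_id[used],
    consensus_mz = mz_sum[used] / cnt[used],
    consensus_rt = rt_sum[used] / cnt[used],
    stringsAsFactors = FALSE)
  feature_matrix(values[, used, drop = FALSE], features,
                 transform_log = "build_feature_matrix")
}
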