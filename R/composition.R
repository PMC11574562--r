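#' Study case-mix tables
#'
#' Printed cohort-composition tables of the multi-cancer case-control study
#' the pipeline is designed around: per-cancer-type counts by sex and
#' clinical stage, and the age-group distribution of cancer cases and
#' non-cancer controls. These tables are the default composition template
#' for [simulate_cohort()] and the basis of the package's in-study
#' arithmetic checks.
#'
#' @return `study_case_mix()` returns a data frame with one row per cancer
#'   type and columns `cancer_type`, `female`, `male`, `total`,
#'   `stage_I` .. `stage_IV` (stage counts are `NA` for cancers of unknown
#'   primary origin, which are not staged). `study_age_mix()` returns a
#'   data frame with columns `age_group`, `cancer`, `normal`.
#'   `study_design_counts()` returns a named list of the study's headline
#'   sample counts (cancer / normal totals and the train-test /
#'   validation split sizes).
#' @examples
#' mix <- study_case_mix()
#' sum(mix$total)                     # 2831 cancer cases over 30 types
#' colSums(mix[, 5:8], na.rm = TRUE)  # stage marginals
#' @export
study_case_mix <- function() {
  path <- system.file("extdata", "cancer_case_mix.tsv",
                      package = "metabodetect", mustWork = TRUE)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname study_case_mix
#' @export
study_age_mix <- function() {
  path <- system.file("extdata", "age_group_mix.tsv",
                      package = "metabodetect", mustWork = TRUE)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname study_case_mix
#' @export
study_design_counts <- function() {
  list(
    n_cancer        = 2831L,
    n_normal        = 3614L,
    n_total         = 6445L,
    n_cancer_types  = 30L,
    train_cancer    = 1445L,
    train_normal    = 1812L,
    validate_cancer = 1386L,
    validate_normal = 1802L
  )
}

#' Scale a case mix down to a target number of cancer samples
#'
#' Allocates `n_cancer` samples across cancer types proportionally to a
#' case-mix table using largest-remainder rounding, so the scaled counts
#' sum exactly to `n_cancer`. Types receiving zero samples are dropped.
#'
#' @param n_cancer total number of cancer samples to allocate.
#' @param case_mix data frame as returned by [study_case_mix()].
#' @param min_types keep at least this many of the largest types by forcing
#'   one sample into any of them that rounding set to zero (default 5).
#' @return named integer vector of per-type counts (names = cancer types),
#'   summing to `n_cancer`.
#' @export
scale_case_mix <- function(n_cancer, case_mix = study_case_mix(),
                           min_types = 5L) {
  stopifnot(n_cancer >= 1, nrow(case_mix) >= 1)
  w <- case_mix$total / sum(case_mix$total)
  raw <- n_cancer * w
  n <- floor(raw)
  rem <- n_cancer - sum(n)
  if (rem > 0) {
    ord <- order(raw - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1L
  }
  # guarantee a minimum spread of types for small cohorts
  top <- order(w, decreasing = TRUE)[seq_len(min(min_types, nrow(case_mix)))]
  for (i in top) {
    if (n[i] == 0L) {
      donor <- which.max(n)
      n[donor] <- n[donor] - 1L
      n[i] <- 1L
    }
  }
  stats::setNames(as.integer(n), case_mix$cancer_type)[n > 0L]
}
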