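#' Configuration for the synthetic LC-MS cohort generator
#'
#' Collects the knobs of the ground-truthed cohort simulator. Defaults
#' describe the study conditions the pipeline targets: a multi-type cancer
#' case mix patterned on the bundled case-mix table, run in several
#' acquisition batches with ppm-scale per-run mass drift, batch-level
#' intensity offsets, and abundance-dependent (MNAR) plus completely random
#' (MCAR) missingness. Intensities are log10-normal per feature; a subset
#' of `n_signature` human-origin metabolites carries a class-specific log10
#' shift (alternating sign across the signature) in cancer samples,
#' attenuated per stage by `stage_attenuation`.
#'
#' @param n_cancer_per_type named integer vector of cancer sample counts
#'   per type; default allocates 400 cases across the bundled case mix via
#'   [scale_case_mix()].
#' @param n_normal number of non-cancer controls (default 400).
#' @param n_metabolites library size used when no library is supplied.
#' @param n_signature number of signature features (default 60).
#' @param effect_size class-specific log10 intensity shift on signature
#'   features in cancer samples (default 0.3).
#' @param stage_attenuation named multiplier on `effect_size` for stages
#'   I, II, III, IV, NS (default all 1: detection strength flat in stage).
#' @param n_batches number of acquisition batches (default 8).
#' @param batch_sd sd of the per-batch Gaussian log10 offset (default 0.3).
#' @param drift_ppm_range interval from which each run's mass drift (ppm)
#'   is drawn (default c(-30, 30)).
#' @param drift_design `"uniform"` (default) draws per-run drift i.i.d.
#'   uniformly over `drift_ppm_range`; `"stratified"` assigns an evenly
#'   spaced grid spanning the range in a random run order, giving a
#'   mean-zero drift design. Anchor-based correction can only recover
#'   drift relative to the cohort consensus (a common offset is
#'   unidentifiable without an external calibrant), so the stratified
#'   design is the right choice when recovered drift is to be compared
#'   with injected truth.
#' @param mcar_rate probability that an otherwise observed peak is dropped
#'   completely at random (default 0.02).
#' @param mnar_threshold_quantile per-feature intensity quantile below
#'   which a peak is dropped as intensity-dependent missingness
#'   (default 0.05; 0 disables MNAR).
#' @param resid_sd sd of the i.i.d. Gaussian residual on log10 abundance
#'   (default 0.2).
#' @param rt_jitter_sd sd of per-peak retention-time jitter, seconds.
#' @param randomize_run_order randomize acquisition order before batch
#'   assignment (default TRUE), so batches are not confounded with class.
#' @param seed integer RNG seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_cancer_per_type = scale_case_mix(400L),
                          n_normal = 400L,
                          n_metabolites = 1000L,
                          n_signature = 60L,
                          effect_size = 0.3,
                          stage_attenuation = c(I = 1, II = 1, III = 1,
                                                IV = 1, NS = 1),
                          n_batches = 8L,
                          batch_sd = 0.3,
                          drift_ppm_range = c(-30, 30),
                          drift_design = c("uniform", "stratified"),
                          mcar_rate = 0.02,
                          mnar_threshold_quantile = 0.05,
                          resid_sd = 0.2,
                          rt_jitter_sd = 2,
                          randomize_run_order = TRUE,
                          seed = 1L) {
  drift_design <- match.arg(drift_design)
  cfg <- list(n_cancer_per_type = n_cancer_per_type, n_normal = n_normal,
              n_metabolites = n_metabolites, n_signature = n_signature,
              effect_size = effect_size,
              stage_attenuation = stage_attenuation, n_batches = n_batches,
              batch_sd = batch_sd, drift_ppm_range = drift_ppm_range,
              drift_design = drift_design,
              mcar_rate = mcar_rate,
              mnar_threshold_quantile = mnar_threshold_quantile,
              resid_sd = resid_sd, rt_jitter_sd = rt_jitter_sd,
              randomize_run_order = randomize_run_order,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(all(cfg$n_cancer_per_type >= 0), cfg$n_normal >= 0,
            cfg$n_metabolites >= 1,
            cfg$n_signature >= 0, cfg$n_signature <= cfg$n_metabolites,
            cfg$n_batches >= 1, cfg$batch_sd >= 0,
            length(cfg$drift_ppm_range) == 2,
            cfg$drift_ppm_range[1] <= cfg$drift_ppm_range[2],
            cfg$mcar_rate >= 0, cfg$mcar_rate <= 1,
            cfg$mnar_threshold_quantile >= 0,
            cfg$mnar_threshold_quantile <= 1,
            cfg$resid_sd >= 0, cfg$rt_jitter_sd >= 0,
            all(c("I", "II", "III", "IV", "NS") %in%
                  names(cfg$stage_attenuation)))
  invisible(cfg)
}

# sample stages for one cancer type from the bundled case-mix proportions
.sample_stages <- function(type, n, case_mix) {
  row <- case_mix[case_mix$cancer_type == type, , drop = FALSE]
  stages <- c("I", "II", "III", "IV")
  if (nrow(row) == 0) return(sample(stages, n, replace = TRUE))
  w <- as.numeric(row[1, paste0("stage_", stages)])
  if (anyNA(w) || sum(w) == 0) return(rep("NS", n))  # unstaged type
  sample(stages, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate a ground-truthed multi-batch LC-MS cohort
#'
#' Generates per-run peak lists, sample metadata, and a truth table for a
#' case-control serum-metabolomics cohort. For each sample the true log10
#' abundance of feature j is `base_log_abundance[j] + batch offset +
#' class effect + N(0, resid_sd)`; observed m/z is the protonated library
#' mass scaled by `1 + drift_ppm/1e6` with one drift value per run; a peak
#' is absent (never zero) when its intensity falls below the feature's
#' MNAR threshold quantile or, independently, with probability
#' `mcar_rate`.
#'
#' @param config a [cohort_config()].
#' @param library a `metabolite_library` (from [simulate_library()]); must
#'   contain at least `config$n_signature` human-origin records.
#' @return a list of class `mcd_cohort` with elements:
#'   \describe{
#'     \item{runs}{list of `peak_list` objects (one per sample), each with
#'       `run_id`, `batch_id` and a `peaks` data frame `mz`, `rt`,
#'       `intensity`, ordered by m/z.}
#'     \item{metadata}{data frame `sample_id`, `class`, `cancer_type`,
#'       `stage`, `age_group`, `sex`, `batch_id` (one row per run; `class =
#'       normal` implies `cancer_type = "none"`, `stage = "NS"`).}
#'     \item{truth}{list: `signature` (data frame of signature metabolite
#'       ids and effect signs), `run_drift` (per-run injected ppm drift),
#'       `missing_cause` (samples x metabolites character matrix:
#'       `"none"`, `"mcar"`, `"mnar"`), `log_abundance` (true log10
#'       abundance matrix before dropout).}
#'   }
#' @examples
#' lib <- simulate_library(40, 0.1, seed = 2)
#' cfg <- cohort_config(n_cancer_per_type = c(Lung = 5, Breast = 5),
#'                      n_normal = 10, n_metabolites = 40, n_signature = 5,
#'                      seed = 2)
#' coh <- simulate_cohort(cfg, lib)
#' table(coh$metadata$class)
#' @export
simulate_cohort <- function(config, library) {
  validate_cohort_config(config)
  if (missing(library) || is.null(library) || nrow(library) == 0) {
    .fail("`library` must be a non-empty metabolite library")
  }
  set.seed(config$seed)
  case_mix <- study_case_mix()
  age_mix <- study_age_mix()

  types <- names(config$n_cancer_per_type)
  n_cancer <- sum(config$n_cancer_per_type)
  n <- n_cancer + config$n_normal
  if (n == 0) .fail("cohort has zero samples")

  cls <- c(rep("cancer", n_cancer), rep("normal", config$n_normal))
  ctype <- c(rep(types, config$n_cancer_per_type),
             rep("none", config$n_normal))
  stage <- character(n)
  i <- 1L
  for (t in types) {
    k <- config$n_cancer_per_type[[t]]
    if (k > 0) {
      stage[i:(i + k - 1L)] <- .sample_stages(t, k, case_mix)
      i <- i + k
    }
  }
  stage[cls == "normal"] <- "NS"

  # demography sampled from the bundled study marginals
  age_group <- character(n)
  age_group[cls == "cancer"] <- sample(age_mix$age_group, n_cancer,
                                       replace = TRUE, prob = age_mix$cancer)
  age_group[cls == "normal"] <- sample(age_mix$age_group, config$n_normal,
                                       replace = TRUE, prob = age_mix$normal)
  sex <- character(n)
  for (t in types) {
    idx <- which(ctype == t)
    row <- case_mix[case_mix$cancer_type == t, , drop = FALSE]
    pf <- if (nrow(row)) row$female[1] / max(row$total[1], 1) else 0.5
    sex[idx] <- sample(c("F", "M"), length(idx), replace = TRUE,
                       prob = c(pf, 1 - pf))
  }
  sex[cls == "normal"] <- sample(c("F", "M"), config$n_normal,
                                 replace = TRUE, prob = c(0.481, 0.519))

  sample_id <- sprintf("S%04d", seq_len(n))
  run_order <- if (config$randomize_run_order) sample.int(n) else seq_len(n)
  batch_of_run <- as.integer(cut(seq_len(n), breaks = config$n_batches,
                                 labels = FALSE))
  batch_id <- integer(n)
  batch_id[run_order] <- batch_of_run

  metadata <- data.frame(sample_id = sample_id, class = cls,
                         cancer_type = ctype, stage = stage,
                         age_group = age_group, sex = sex,
                         batch_id = sprintf("B%02d", batch_id),
                         stringsAsFactors = FALSE)

  p <- nrow(library)
  human_idx <- which(library$origin == "human")
  if (config$n_signature > length(human_idx)) {
    .fail("library has fewer human-origin records than `n_signature`")
  }
  sig_idx <- sort(sample(human_idx, config$n_signature))
  sig_sign <- rep_len(c(1, -1), config$n_signature)

  batch_offset <- rnorm(config$n_batches, 0, config$batch_sd)
  stage_mult <- config$stage_attenuation[stage]
  stage_mult[is.na(stage_mult)] <- 1

  logab <- matrix(rep(library$base_log_abundance, each = n), n, p)
  logab <- logab + batch_offset[batch_id]
  if (config$n_signature > 0 && n_cancer > 0) {
    is_cancer <- cls == "cancer"
    shift <- outer(ifelse(is_cancer, config$effect_size, 0) * stage_mult,
                   sig_sign)
    logab[, sig_idx] <- logab[, sig_idx] + shift
  }
  logab <- logab + matrix(rnorm(n * p, 0, config$resid_sd), n, p)
  dimnames(logab) <- list(sample_id, library$metabolite_id)
  intensity <- 10^logab

  # missingness: MNAR below the per-feature threshold quantile, then MCAR
  missing_cause <- matrix("none", n, p, dimnames = dimnames(logab))
  if (config$mnar_threshold_quantile > 0) {
    thr <- apply(intensity, 2, quantile,
                 probs = config$mnar_threshold_quantile)
    mnar <- sweep(intensity, 2, thr, "<")
    missing_cause[mnar] <- "mnar"
  }
  if (config$mcar_rate > 0) {
    mcar <- matrix(runif(n * p) < config$mcar_rate, n, p) &
      missing_cause == "none"
    missing_cause[mcar] <- "mcar"
  }

  drift <- if (identical(config$drift_design, "stratified") && n > 1) {
    sample(seq(config$drift_ppm_range[1], config$drift_ppm_range[2],
               length.out = n))
  } else {
    runif(n, config$drift_ppm_range[1], config$drift_ppm_range[2])
  }
  mz_true <- library$monoisotopic_mass + PROTON_MASS
  rt_jitter <- matrix(rnorm(n * p, 0, config$rt_jitter_sd), n, p)

  runs <- vector("list", n)
  for (s in seq_len(n)) {
    obs <- which(missing_cause[s, ] == "none")
    mz <- mz_true[obs] * (1 + drift[s] / 1e6)
    rt <- pmax(library$nominal_rt[obs] + rt_jitter[s, obs], 0)
    ord <- order(mz)
    runs[[s]] <- structure(
      list(run_id = sample_id[s], batch_id = metadata$batch_id[s],
           peaks = data.frame(mz = mz[ord], rt = rt[ord],
                              intensity = intensity[s, obs][ord])),
      class = "peak_list")
  }

  truth <- list(
    signature = data.frame(metabolite_id = library$metabolite_id[sig_idx],
                           sign = sig_sign, stringsAsFactors = FALSE),
    run_drift = data.frame(run_id = sample_id, drift_ppm = drift,
                           stringsAsFactors = FALSE),
    missing_cause = missing_cause,
    log_abundance = logab
  )
  structure(list(runs = runs, metadata = metadata, truth = truth,
                 library = library, config = config),
            class = "mcd_cohort")
}

#' @export
print.mcd_cohort <- function(x, ...) {
  cat("Synthetic LC-MS cohort:", length(x$runs), "runs,",
      nrow(x$library), "library metabolites\n")
  print(table(x$metadata$class))
  invisible(x)
}

#' Write a simulated cohort to disk as plain-text tables
#'
#' One CSV per run (`mz,rt,intensity`), a metadata CSV, the library TSV,
#' and the truth tables (signature CSV and per-run drift CSV).
#'
#' @param cohort an `mcd_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  for (r in cohort$runs) {
    write.csv(r$peaks, file.path(dir, "runs", paste0(r$run_id, ".csv")),
              row.names = FALSE)
  }
  write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE)
  write_library(cohort$library, file.path(dir, "library.tsv"))
  write.csv(cohort$truth$signature, file.path(dir, "truth_signature.csv"),
            row.names = FALSE)
  write.csv(cohort$truth$run_drift, file.path(dir, "truth_drift.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read peak-list CSVs from a directory
#'
#' @param dir directory containing per-run `*.csv` peak lists in the
#'   `mz,rt,intensity` dialect written by [write_cohort()].
#' @param metadata optional metadata data frame supplying batch ids.
#' @return list of `peak_list` objects.
#' @export
read_runs <- function(dir, metadata = NULL) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  lapply(files, function(f) {
    id <- sub("\\.csv$", "", basename(f))
    batch <- if (!is.null(metadata)) {
      metadata$batch_id[match(id, metadata$sample_id)]
    } else NA_character_
    structure(list(run_id = id, batch_id = batch,
                   peaks = read.csv(f, stringsAsFactors = FALSE)),
              class = "peak_list")
  })
}
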