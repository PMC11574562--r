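test_that("curation filter keeps exactly the human-origin features", {
  lib <- hand_library(c(100, 200, 300, 400, 500),
                      origin = c("human", "drug", "human", "human",
                                 "human"))
  vals <- matrix(runif(10, 1, 2), 2, 5)
  fm <- hand_matrix(vals)
  out <- filter_nonhuman(fm, lib)
  expect_equal(ncol(out$values), 4)
  expect_false("MB00002" %in% out$features$metabolite_id)
  expect_equal(nrow(out$values), 2)

  all_human <- filter_nonhuman(out, lib)
  expect_equal(all_human$values, out$values)
  expect_gt(length(all_human$transform_log), length(out$transform_log))

  bad <- hand_matrix(vals, ids = c(sprintf("MB%05d", 1:4), "MBXXXXX"))
  expect_error(filter_nonhuman(bad, lib), "MBXXXXX")
})

test_that("generator fraction flows through the curation filter exactly", {
  lib <- simulate_library(100, fraction_nonhuman = 0.2, seed = 14)
  vals <- matrix(runif(300, 1, 2), 3, 100)
  fm <- hand_matrix(vals, ids = lib$metabolite_id)
  out <- filter_nonhuman(fm, lib)
  expect_equal(ncol(out$values), 80)
})

test_that("prevalence filter is boundary-inclusive; abundance mode matches a hand ranking", {
  vals <- matrix(1, 10, 3)
  vals[, 1] <- c(1, rep(NA, 9))          # present in 1/10 -> dropped
  vals[, 2] <- c(1, 2, rep(NA, 8))       # present in 2/10 -> kept
  fm <- hand_matrix(vals)
  out <- filter_features(fm, mode = "prevalence",
                         min_presence_fraction = 0.2)
  expect_equal(out$features$metabolite_id, c("MB00002", "MB00003"))

  set.seed(15)
  vals2 <- matrix(10^runif(50, 1, 5), 5, 10)
  fm2 <- hand_matrix(vals2)
  out2 <- filter_features(fm2, mode = "abundance_percentile",
                          k_percent = 20)
  # hand oracle: drop the floor(0.2 * 10) = 2 lowest mean-log10 features
  means <- colMeans(log10(vals2))
  drop_ids <- sprintf("MB%05d", order(means)[1:2])
  expect_equal(ncol(out2$values), 8)
  expect_false(any(drop_ids %in% out2$features$metabolite_id))

  expect_error(filter_features(fm, mode = "prevalence",
                               min_presence_fraction = 1.01))
})

test_that("log10 scaling transforms observed cells only, once", {
  vals <- matrix(c(100, 1, NA, 10), 2, 2)
  fm <- hand_matrix(vals)
  out <- log_transform(fm)
  expect_equal(out$values[1, 1], 2)
  expect_equal(out$values[2, 1], 0)
  expect_true(is.na(out$values[1, 2]))
  expect_error(log_transform(out), "already")
  fm_bad <- hand_matrix(matrix(c(-1, 2, 3, 4), 2, 2))
  expect_error(log_transform(fm_bad), "> 0")
})

test_that("quantile reference matches classical quantile normalization on complete data", {
  fm <- hand_matrix(rbind(c(1, 3, 5), c(2, 4, 6)),
                    transform_log = "log10")
  ref <- fit_quantile_reference(fm)
  expect_equal(ref$reference_quantiles, c(1.5, 3.5, 5.5))

  same <- hand_matrix(rbind(c(2, 1, 3), c(3, 1, 2)),
                      transform_log = "log10")
  ref2 <- fit_quantile_reference(same)
  expect_equal(ref2$reference_quantiles, c(1, 2, 3))

  single <- hand_matrix(matrix(c(4, 6, 8), 3, 1),
                        transform_log = "log10")
  expect_error(fit_quantile_reference(single), "< 2 observed")
})

test_that("normalized complete samples reproduce the reference exactly", {
  set.seed(16)
  fm <- hand_matrix(matrix(rnorm(200, 5), 10, 20),
                    transform_log = "log10")
  ref <- fit_quantile_reference(fm)
  out <- normalize_quantiles(fm, ref)
  for (s in 1:10) {
    expect_equal(sort(out$values[s, ]), ref$reference_quantiles,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # rank preservation within each sample
  for (s in 1:10) {
    expect_equal(order(out$values[s, ]), order(fm$values[s, ]))
  }
})

test_that("tied values map to the mean of the reference quantiles they span", {
  fm <- hand_matrix(rbind(c(1, 3, 5), c(2, 4, 6)),
                    transform_log = "log10")
  ref <- fit_quantile_reference(fm)   # 1.5 3.5 5.5
  const <- hand_matrix(matrix(2, 1, 3), transform_log = "log10")
  out <- normalize_quantiles(const, ref)
  expect_equal(unname(out$values[1, ]), rep(mean(c(1.5, 3.5, 5.5)), 3))
})

test_that("normalization is rank-invariant and single-sample consistent", {
  set.seed(17)
  fm <- hand_matrix(matrix(rnorm(60, 5), 4, 15), transform_log = "log10")
  ref <- fit_quantile_reference(fm)
  # two samples with identical rank order but different scales
  a <- fm$values[1, ]
  b <- 10 + 3 * a
  na <- normalize_quantiles(a, ref)
  nb <- normalize_quantiles(b, ref)
  expect_equal(na, nb)

  # row-by-row equals whole-matrix, including under missingness
  fm$values[cbind(c(1, 2, 3), c(5, 9, 2))] <- NA
  whole <- normalize_quantiles(fm, ref)
  for (s in 1:4) {
    expect_equal(normalize_quantiles(fm$values[s, ], ref),
                 whole$values[s, ])
  }
  expect_true(all(is.na(whole$values[cbind(c(1, 2, 3), c(5, 9, 2))])))

  wrong <- hand_matrix(matrix(1, 2, 3), ids = c("X1", "X2", "X3"),
                       transform_log = "log10")
  expect_error(normalize_quantiles(wrong, ref), "feature order")
})

test_that("normalization removes most of the batch effect in per-sample means", {
  lib <- simulate_library(120, 0, seed = 18)
  cfg <- cohort_config(n_cancer_per_type = c(Lung = 30), n_normal = 30,
                       n_metabolites = 120, n_signature = 5,
                       n_batches = 4, batch_sd = 0.3, seed = 18)
  coh <- simulate_cohort(cfg, lib)
  an <- detect_vlm_anchors(coh$runs, ppm_window = 45, min_presence = 0.9)
  fm <- build_feature_matrix(lapply(coh$runs, correct_masses,
                                    anchors = an), lib)
  fm <- log_transform(fm)
  batch <- coh$metadata$batch_id[match(rownames(fm$values),
                                       coh$metadata$sample_id)]
  share <- function(m) {
    sm <- rowMeans(m, na.rm = TRUE)
    gm <- mean(sm)
    ssb <- sum(tapply(sm, batch, function(v) {
      length(v) * (mean(v) - gm)^2
    }))
    ssb / sum((sm - gm)^2)
  }
  ref <- fit_quantile_reference(fm)
  fmn <- normalize_quantiles(fm, ref)
  expect_lte(share(fmn$values), 0.5 * share(fm$values))
})

test_that("normalization reference round-trips through JSON", {
  fm <- hand_matrix(rbind(c(1, 3, 5), c(2, 4, 6)),
                    transform_log = "log10")
  ref <- fit_quantile_reference(fm)
  path <- withr::local_tempfile(fileext = ".json")
  write_normalization_reference(ref, path)
  ref2 <- read_normalization_reference(path)
  expect_equal(ref2$reference_quantiles, ref$reference_quantiles)
  expect_equal(ref2$feature_order, ref$feature_order)
})
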