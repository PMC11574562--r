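test_that("library generator enforces origin fractions, spacing and determinism", {
  lib0 <- simulate_library(10, fraction_nonhuman = 0, seed = 1)
  expect_equal(nrow(lib0), 10)
  expect_true(all(lib0$origin == "human"))

  lib <- simulate_library(100, fraction_nonhuman = 0.2, seed = 1)
  expect_equal(sum(lib$origin != "human"), 20)
  expect_false(anyDuplicated(lib$metabolite_id) > 0)
  expect_true(all(lib$monoisotopic_mass > 0))
  # relative spacing above the documented minimum (100 ppm default)
  rel_gap <- diff(lib$monoisotopic_mass) / head(lib$monoisotopic_mass, -1)
  expect_true(all(rel_gap > 100e-6))

  a <- simulate_library(50, 0.3, seed = 7)
  b <- simulate_library(50, 0.3, seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  expect_error(simulate_library(0), "positive")
  expect_error(simulate_library(10, fraction_nonhuman = 1), "fraction")
})

test_that("cohort composition and metadata invariants hold", {
  lib <- simulate_library(30, 0, seed = 2)
  cfg <- cohort_config(n_cancer_per_type = c(Lung = 0, Breast = 0),
                       n_normal = 12, n_metabolites = 30, n_signature = 4,
                       seed = 2)
  coh <- simulate_cohort(cfg, lib)
  expect_true(all(coh$metadata$class == "normal"))
  expect_true(all(coh$metadata$cancer_type == "none"))
  expect_true(all(coh$metadata$stage == "NS"))

  cfg2 <- cohort_config(n_cancer_per_type = c(Lung = 7, Breast = 5),
                        n_normal = 10, n_metabolites = 30, n_signature = 4,
                        seed = 3)
  coh2 <- simulate_cohort(cfg2, lib)
  expect_equal(sum(coh2$metadata$cancer_type == "Lung"), 7)
  expect_equal(sum(coh2$metadata$cancer_type == "Breast"), 5)
  expect_equal(sum(coh2$metadata$class == "normal"), 10)
  # breast cancer cases are female in the bundled case mix
  expect_true(all(coh2$metadata$sex[coh2$metadata$cancer_type ==
                                      "Breast"] == "F"))
  expect_error(simulate_cohort(cfg2, lib[0, ]), "non-empty")
})

test_that("zero drift leaves observed m/z exactly at protonated library masses", {
  lib <- simulate_library(25, 0, seed = 4)
  cfg <- cohort_config(n_cancer_per_type = c(Lung = 2), n_normal = 2,
                       n_metabolites = 25, n_signature = 2,
                       drift_ppm_range = c(0, 0), mcar_rate = 0,
                       mnar_threshold_quantile = 0, seed = 4)
  coh <- simulate_cohort(cfg, lib)
  expected <- sort(lib$monoisotopic_mass + 1.00727646)
  for (r in coh$runs) expect_equal(r$peaks$mz, expected)
})

test_that("generator is deterministic for a fixed config", {
  lib <- simulate_library(20, 0.1, seed = 5)
  cfg <- cohort_config(n_cancer_per_type = c(Lung = 5), n_normal = 5,
                       n_metabolites = 20, n_signature = 3, seed = 5)
  a <- simulate_cohort(cfg, lib)
  b <- simulate_cohort(cfg, lib)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("MCAR dropout rate matches its nominal probability", {
  lib <- simulate_library(300, 0, seed = 6)
  cfg <- cohort_config(n_cancer_per_type = c(Lung = 0), n_normal = 50,
                       n_metabolites = 300, n_signature = 0,
                       mcar_rate = 0.1, mnar_threshold_quantile = 0,
                       seed = 6)
  coh <- simulate_cohort(cfg, lib)
  cells <- length(coh$truth$missing_cause)
  expect_gte(cells, 10000)
  frac <- mean(coh$truth$missing_cause == "mcar")
  se <- sqrt(0.1 * 0.9 / cells)
  expect_lt(abs(frac - 0.1), 3 * se)
  expect_true(all(coh$truth$missing_cause %in% c("none", "mcar")))
})

test_that("class separation of signature features is monotone in effect size", {
  lib <- simulate_library(40, 0, seed = 8)
  sep <- vapply(c(0, 0.25, 0.5), function(es) {
    cfg <- cohort_config(n_cancer_per_type = c(Lung = 40), n_normal = 40,
                         n_metabolites = 40, n_signature = 6,
                         effect_size = es, batch_sd = 0, seed = 8)
    coh <- simulate_cohort(cfg, lib)
    sig <- coh$truth$signature$metabolite_id
    canc <- coh$metadata$class == "cancer"
    d <- vapply(sig, function(id) {
      v <- coh$truth$log_abundance[, id]
      abs(mean(v[canc]) - mean(v[!canc])) / sd(v)
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("null effect leaves signature class means equal within sampling error", {
  lib <- simulate_library(20, 0, seed = 9)
  cfg <- cohort_config(n_cancer_per_type = c(Lung = 500), n_normal = 500,
                       n_metabolites = 20, n_signature = 5,
                       effect_size = 0, mcar_rate = 0,
                       mnar_threshold_quantile = 0, batch_sd = 0, seed = 9)
  coh <- simulate_cohort(cfg, lib)
  canc <- coh$metadata$class == "cancer"
  for (id in coh$truth$signature$metabolite_id) {
    v <- coh$truth$log_abundance[, id]
    se <- sqrt(var(v[canc]) / sum(canc) + var(v[!canc]) / sum(!canc))
    expect_lt(abs(mean(v[canc]) - mean(v[!canc])), 3 * se)
  }
})

test_that("cohort round-trips through the plain-text dialects", {
  lib <- simulate_library(15, 0.2, seed = 10)
  cfg <- cohort_config(n_cancer_per_type = c(Lung = 3), n_normal = 3,
                       n_metabolites = 15, n_signature = 2, seed = 10)
  coh <- simulate_cohort(cfg, lib)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  runs <- read_runs(file.path(dir, "runs"), coh$metadata)
  expect_equal(length(runs), 6)
  ids <- vapply(runs, `[[`, character(1), "run_id")
  orig <- coh$runs[match(ids, vapply(coh$runs, `[[`, character(1),
                                     "run_id"))]
  for (i in seq_along(runs)) {
    expect_equal(runs[[i]]$peaks$mz, orig[[i]]$peaks$mz, tolerance = 1e-12)
  }
  lib2 <- read_library(file.path(dir, "library.tsv"))
  expect_equal(lib2$monoisotopic_mass, lib$monoisotopic_mass,
               tolerance = 1e-12)
  expect_equal(lib2$origin, lib$origin)
})
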