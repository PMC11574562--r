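test_that("RBF kernel matches its closed form and is symmetric", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), 3), 1)
  # ||x - x'||^2 = 2 sigma^2 -> exp(-1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), sigma = 1), exp(-1))
  set.seed(30)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(4); s <- runif(1, 0.5, 3)
    expect_equal(rbf_kernel(x, y, s), rbf_kernel(y, x, s))
    expect_gt(rbf_kernel(x, y, s), 0)
    expect_lte(rbf_kernel(x, y, s), 1)
  }
  expect_error(rbf_kernel(1, 1, 0), "positive")
})

test_that("a linearly separable toy set is classified perfectly", {
  set.seed(31)
  x <- rbind(matrix(rnorm(8, sd = 0.1), 4) + 3,
             matrix(rnorm(8, sd = 0.1), 4) - 3)
  labels <- rep(c("cancer", "normal"), each = 4)
  fit <- svm_rbf(x, labels, C = 10, sigma = 1)
  expect_equal(predict(fit, x, type = "class"), labels)
  expect_error(svm_rbf(x, rep("cancer", 8)), "both classes")
})

test_that("SMO dual objective matches an independent QP solution", {
  skip_if_not_installed("kernlab")
  set.seed(32)
  x <- rbind(matrix(rnorm(6, sd = 0.6), 3) + 1,
             matrix(rnorm(6, sd = 0.6), 3) - 1)
  y <- c(1, 1, 1, -1, -1, -1)
  C <- 1; sigma <- 1.5
  fit <- svm_rbf(x, y, C = C, sigma = sigma, tol = 1e-6)

  K <- outer(seq_len(6), seq_len(6),
             Vectorize(function(i, j) rbf_kernel(x[i, ], x[j, ], sigma)))
  H <- K * (y %o% y)
  qp <- kernlab::ipop(c = rep(-1, 6), H = H, A = matrix(y, 1),
                      b = 0, r = 0, l = rep(0, 6), u = rep(C, 6),
                      sigf = 9)
  a <- kernlab::primal(qp)
  obj_ref <- sum(a) - 0.5 * drop(t(a) %*% H %*% a)
  expect_lt(abs(fit$objective - obj_ref), 1e-4)

  # KKT feasibility of the returned model
  expect_true(all(fit$alpha >= -1e-8 & fit$alpha <= C + 1e-8))
  expect_lt(abs(sum(fit$alpha * fit$y)), 1e-6)
})

test_that("duplicating the training set leaves the decision function unchanged", {
  set.seed(33)
  sep <- separable_matrix(n_per_class = 10, p = 3, gap = 3, seed = 33)
  fit1 <- svm_rbf(sep$x, sep$labels, C = 1, sigma = 2, tol = 1e-6)
  fit2 <- svm_rbf(rbind(sep$x, sep$x), rep(sep$labels, 2), C = 0.5,
                  sigma = 2, tol = 1e-6)
  probes <- matrix(rnorm(60), 20, 3)
  expect_equal(decision_score(fit1, probes), decision_score(fit2, probes),
               tolerance = 1e-6)
})

test_that("decision scores follow the support-vector expansion exactly", {
  # single support vector, alpha = 1, y = +1, b = 0 -> F(x1) = 1
  m <- structure(list(sv = matrix(c(1, 2), 1), alpha = 1, y = 1, b = 0,
                      sigma = 1, C = 1), class = "svm_rbf")
  expect_equal(decision_score(m, c(1, 2)), 1)
  m$b <- -0.5
  expect_equal(decision_score(m, c(1, 2)), 0.5)

  set.seed(34)
  sep <- separable_matrix(n_per_class = 15, p = 4, gap = 2, seed = 34)
  fit <- svm_rbf(sep$x, sep$labels, C = 1, sigma = 1.5)
  probes <- matrix(rnorm(400), 100, 4)
  brute <- apply(probes, 1, function(p) {
    sum(vapply(seq_along(fit$alpha), function(i) {
      fit$alpha[i] * fit$y[i] * rbf_kernel(p, fit$sv[i, ], fit$sigma)
    }, numeric(1))) + fit$b
  })
  expect_equal(decision_score(fit, probes), brute, tolerance = 1e-10)
  expect_error(decision_score(fit, c(1, 2)), "features")
})

test_that("score cutoff calls cancer strictly above zero", {
  expect_equal(classify_scores(1.3), "cancer")
  expect_equal(classify_scores(-0.2), "normal")
  expect_equal(classify_scores(0), "normal")
  expect_equal(classify_scores(c(0.1, 0, -1)),
               c("cancer", "normal", "normal"))
})

test_that("margin support vectors reproduce their labels (KKT check)", {
  set.seed(35)
  x <- rbind(matrix(rnorm(40), 20) + 1.2, matrix(rnorm(40), 20) - 1.2)
  labels <- rep(c(1, -1), each = 20)
  fit <- svm_rbf(x, labels, C = 5, sigma = 2, tol = 1e-6)
  margin <- which(fit$alpha > 1e-6 & fit$alpha < 5 - 1e-6)
  if (length(margin)) {
    f <- decision_score(fit, fit$sv[margin, , drop = FALSE])
    expect_equal(f, fit$y[margin], tolerance = 1e-3)
  }
})

test_that("grid search returns the maximizer with deterministic bookkeeping", {
  sep <- separable_matrix(n_per_class = 10, p = 4, gap = 4, seed = 36)
  one <- grid_search_svm(sep$x, sep$labels, c_grid = 2, sigma_grid = 3,
                         k_folds = 5, seed = 1)
  expect_equal(one$best_C, 2)
  expect_equal(one$best_sigma, 3)
  expect_equal(nrow(one$cv_table), 1)

  gs1 <- grid_search_svm(sep$x, sep$labels, k_folds = 5, seed = 9)
  gs2 <- grid_search_svm(sep$x, sep$labels, k_folds = 5, seed = 9)
  expect_identical(gs1$cv_table, gs2$cv_table)
  expect_equal(max(gs1$cv_table$cv_accuracy), 100)
  expect_error(grid_search_svm(sep$x, sep$labels, c_grid = numeric(0)),
               "non-empty")
})

test_that("20 folds of 40 samples are disjoint test pairs covering everything", {
  labels <- rep(c("cancer", "normal"), each = 20)
  fold <- make_folds(labels, 20, stratified = TRUE, seed = 4)
  expect_equal(sort(unique(fold)), 1:20)
  expect_true(all(table(fold) == 2))
  expect_true(all(table(fold, labels) == 1))  # one of each class per fold
  expect_error(make_folds(rep(c("a", "b"), c(5, 35)), 20), "fewer")
})

test_that("k-fold metrics equal a hand-computed loop on a toy problem", {
  sep <- separable_matrix(n_per_class = 6, p = 2, gap = 5, seed = 37)
  cv <- kfold_cv(sep$x, sep$labels, C = 10, sigma = 2, k_folds = 2,
                 seed = 5)
  fold <- cv$fold_assignment
  for (f in 1:2) {
    tr <- fold != f; te <- fold == f
    fit <- svm_rbf(sep$x[tr, ], sep$labels[tr], C = 10, sigma = 2,
                   tol = 1e-3)
    pred <- predict(fit, sep$x[te, ], type = "class")
    truth <- sep$labels[te]
    sens <- 100 * sum(pred == "cancer" & truth == "cancer") /
      sum(truth == "cancer")
    acc <- 100 * mean(pred == truth)
    expect_equal(cv$folds$sensitivity[f], sens)
    expect_equal(cv$folds$accuracy[f], acc)
  }
  # perfectly separable: every fold at full sensitivity
  expect_true(all(cv$folds$sensitivity == 100))
})

test_that("confusion metrics and AUC follow their defining formulas", {
  scores <- c(rep(1, 9), -1, rep(-1, 8), 1, 1)
  labels <- c(rep("cancer", 10), rep("normal", 10))
  rep_ <- evaluate_scores(scores, labels)
  expect_equal(rep_$TP, 9); expect_equal(rep_$FN, 1)
  expect_equal(rep_$TN, 8); expect_equal(rep_$FP, 2)
  expect_equal(rep_$sensitivity, 90)
  expect_equal(rep_$specificity, 80)
  expect_equal(rep_$accuracy, 85)

  perf <- evaluate_scores(c(2, 3, -1, -2), c("cancer", "cancer",
                                             "normal", "normal"))
  expect_equal(perf$auc, 1.0)

  r4 <- evaluate_scores(c(0.9, 0.7, 0.6, 0.2),
                        c("cancer", "normal", "cancer", "normal"))
  expect_equal(r4$auc, 0.75)
  expect_error(evaluate_scores(1:3, c("cancer", "normal")), "length")
})

test_that("rank-based AUC equals brute-force pair counting with ties", {
  set.seed(38)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    labels <- sample(c("cancer", "normal"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    score <- round(rnorm(n), 1)   # coarse scores force ties
    pos <- score[labels == "cancer"]; neg <- score[labels == "normal"]
    brute <- mean(outer(pos, neg, function(a, b) {
      (a > b) + 0.5 * (a == b)
    }))
    expect_equal(auc_rank(score, labels == "cancer"), brute)
  }
})

test_that("subgroup sensitivities come with valid Wilson intervals", {
  set.seed(39)
  n <- 60
  labels <- rep(c("cancer", "normal"), each = n / 2)
  scores <- ifelse(labels == "cancer", rnorm(n, 1), rnorm(n, -1))
  meta <- data.frame(
    cancer_type = ifelse(labels == "cancer",
                         sample(c("Lung", "Breast"), n, TRUE), "none"),
    stage = ifelse(labels == "cancer",
                   sample(c("I", "II"), n, TRUE), "NS"),
    age_group = sample(c("20-30", "31-40"), n, TRUE))
  rep_ <- evaluate_scores(scores, labels, metadata = meta)
  pg <- rep_$per_group
  expect_true(all(c("cancer_type", "stage", "age_group") %in%
                    pg$group_key))
  expect_true(all(pg$ci_low <= pg$sensitivity + 1e-9))
  expect_true(all(pg$ci_high >= pg$sensitivity - 1e-9))
  expect_true(all(pg$ci_low >= 0 & pg$ci_high <= 100))
  # Wilson interval against a direct computation
  ci <- wilson_ci(9, 10)
  z <- qnorm(0.975); p <- 0.9; n10 <- 10
  center <- (p + z^2 / 20) / (1 + z^2 / 10)
  half <- z * sqrt(p * 0.1 / 10 + z^2 / 400) / (1 + z^2 / 10)
  expect_equal(ci, c(center - half, center + half))
})

test_that("RFE ranks the only informative feature first", {
  set.seed(40)
  n <- 60
  cls <- rep(c(1, -1), each = n / 2)
  x <- cbind(A = cls + rnorm(n, sd = 0.2),
             B = rnorm(n), C = rnorm(n))
  r <- rfe_rank(x, cls, C = 1, sigma = 1.5, step = 1, seed = 2)
  expect_equal(r$ranking$feature[r$ranking$rank == 1], "A")
  expect_equal(nrow(r$trace), 3)

  # two features, step 1: a permutation ranked over two rounds
  r2 <- rfe_rank(x[, 1:2], cls, C = 1, sigma = 1.5, step = 1, seed = 2)
  expect_setequal(r2$ranking$feature, c("A", "B"))
  expect_setequal(r2$ranking$rank, 1:2)
  expect_equal(max(r2$trace$round), 2)
})

test_that("a constant feature is eliminated before any informative one", {
  set.seed(41)
  n <- 50
  cls <- rep(c(1, -1), each = n / 2)
  x <- cbind(sig1 = cls + rnorm(n, 0.1), sig2 = -cls + rnorm(n, 0.1),
             flat = rep(2, n))
  r <- rfe_rank(x, cls, C = 1, sigma = 2, step = 1, seed = 3)
  rk <- r$ranking
  expect_equal(rk$feature[which.max(rk$rank)], "flat")
  expect_equal(rk$round_eliminated[rk$feature == "flat"], 1L)
})

test_that("SVM model bundle round-trips through disk", {
  sep <- separable_matrix(n_per_class = 8, p = 3, gap = 3, seed = 42)
  fit <- svm_rbf(sep$x, sep$labels, C = 2, sigma = 1.5)
  dir <- withr::local_tempdir()
  write_svm_model(fit, dir)
  fit2 <- read_svm_model(dir)
  probes <- matrix(rnorm(30), 10, 3)
  expect_equal(decision_score(fit2, probes), decision_score(fit, probes),
               tolerance = 1e-12)
})
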