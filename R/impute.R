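#' Gradient-boosted tree regressor backend for MICE
#'
#' The chained-equations imputer is parameterized over a regression
#' backend through a small interface: `fit(X, y)` returns a fitted
#' regressor, `predict(model, X)` returns numeric predictions, and
#' `save`/`load` serialize one regressor to/from a file. The default
#' backend is gradient-boosted regression trees (xgboost) with small
#' depth, run single-threaded so fits are deterministic.
#'
#' @param nrounds number of boosting rounds (default 40).
#' @param max_depth tree depth (default 3).
#' @param eta learning rate (default 0.3).
#' @return a list implementing the regressor interface.
#' @export
xgb_regressor <- function(nrounds = 40, max_depth = 3, eta = 0.3) {
  params <- list(max_depth = max_depth, eta = eta,
                 objective = "reg:squarederror", nthread = 1,
                 tree_method = "hist")
  list(
    fit = function(X, y) {
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(params = params, data = dm, nrounds = nrounds,
                         verbose = 0)
    },
    predict = function(model, X) {
      predict(model, xgboost::xgb.DMatrix(X, nthread = 1))
    },
    save = function(model, path) xgboost::xgb.save(model, path),
    load = function(path) xgboost::xgb.load(path),
    spec = list(backend = "xgboost", nrounds = nrounds,
                max_depth = max_depth, eta = eta)
  )
}

# visit priority over all features: ascending training-missingness count,
# ties by metabolite id
.visit_priority <- function(miss_count, ids) order(miss_count, ids)

#' Fit a chained-equations (MICE) imputation model
#'
#' Missing cells are initialized with their feature means. Features are
#' then visited in ascending order of missingness (ties by metabolite id):
#' at each visit a tree-ensemble regressor is fit with the feature's
#' observed cells as targets and the current working values of the other
#' features as predictors, and the feature's missing cells are overwritten
#' with its predictions. A full pass over the visited features is one
#' iteration. Iteration stops at `max_iterations` (the pipeline default is
#' five) or earlier when the sum of squared differences between successive
#' imputations grows, in which case the grown iteration is rolled back.
#' Observed cells are never modified.
#'
#' To keep fitting tractable on matrices with ~1000 features, each
#' feature's regressor uses only its `n_predictors` most correlated
#' partner features (absolute Pearson correlation on the mean-initialized
#' matrix) as predictors.
#'
#' After convergence a frozen regressor is (re)fit for every retained
#' feature on the completed matrix, so single test samples can be imputed
#' later without refitting.
#'
#' @param fm a normalized [feature_matrix()]; every feature needs at least
#'   one observed value.
#' @param max_iterations maximum chained-equation iterations (default 5).
#' @param seed integer RNG seed.
#' @param regressor a regressor interface, see [xgb_regressor()].
#' @param n_predictors number of preselected predictor features per target
#'   (default 20).
#' @return list with `model` (class `mice_model`) and `completed` (the
#'   completed `feature_matrix`).
#' @export
fit_mice <- function(fm, max_iterations = 5, seed = 1L,
                     regressor = xgb_regressor(), n_predictors = 20) {
  x <- fm$values
  n <- nrow(x); p <- ncol(x)
  ids <- fm$features$metabolite_id
  miss <- is.na(x)
  if (any(colSums(!miss) == 0)) {
    .fail("feature(s) with zero observed values cannot be initialized: ",
          paste(ids[colSums(!miss) == 0], collapse = ", "))
  }
  set.seed(seed)
  feature_means <- colMeans(x, na.rm = TRUE)
  miss_count <- colSums(miss)
  priority <- .visit_priority(miss_count, ids)
  visit <- priority[miss_count[priority] > 0]

  n_predictors <- min(n_predictors, p - 1L)
  W <- x
  for (j in seq_len(p)) W[miss[, j], j] <- feature_means[j]

  # predictor preselection on the mean-initialized matrix
  cm <- abs(suppressWarnings(cor(W)))
  diag(cm) <- -Inf
  cm[is.na(cm)] <- -Inf
  pred_idx <- lapply(seq_len(p), function(j) {
    sort(order(cm[, j], decreasing = TRUE)[seq_len(n_predictors)])
  })

  ssd_trace <- numeric(0)
  n_iter <- 0L
  if (length(visit) > 0) {
    prev_imp <- W[miss]
    for (it in seq_len(max_iterations)) {
      snapshot <- W
      for (j in visit) {
        obs_j <- which(!miss[, j])
        pj <- pred_idx[[j]]
        fit <- regressor$fit(W[obs_j, pj, drop = FALSE], x[obs_j, j])
        mis_j <- which(miss[, j])
        W[mis_j, j] <- regressor$predict(fit,
                                         W[mis_j, pj, drop = FALSE])
      }
      imp <- W[miss]
      ssd <- sum((imp - prev_imp)^2)
      if (it >= 2 && ssd > ssd_trace[length(ssd_trace)]) {
        W <- snapshot              # roll back the iteration that grew
        break
      }
      ssd_trace <- c(ssd_trace, ssd)
      prev_imp <- imp
      n_iter <- it
    }
  }

  # frozen per-feature regressors on the completed matrix
  regressors <- vector("list", p)
  for (j in seq_len(p)) {
    obs_j <- which(!miss[, j])
    regressors[[j]] <- regressor$fit(W[obs_j, pred_idx[[j]], drop = FALSE],
                                     x[obs_j, j])
  }

  completed <- fm
  completed$values <- W
  completed <- .log_transform(completed,
                              sprintf("mice_imputed(iters=%d)", n_iter))
  model <- structure(list(
    feature_means = feature_means, regressors = regressors,
    pred_idx = pred_idx, visit_priority = priority,
    feature_order = ids, n_iterations_run = n_iter,
    max_iterations = max_iterations, ssd_trace = ssd_trace,
    seed = seed, regressor = regressor), class = "mice_model")
  list(model = model, completed = completed)
}

#' @export
print.mice_model <- function(x, ...) {
  cat("mice_model:", length(x$feature_order), "features,",
      x$n_iterations_run, "iterations run (",
      x$regressor$spec$backend, "backend )\n")
  invisible(x)
}

#' Impute missing values with a frozen MICE model
#'
#' Each sample is completed independently: missing cells start at the
#' model's feature means, then for the model's number of iterations each
#' missing feature is predicted once per pass by its frozen regressor (no
#' refitting), in the model's visit order. Observed cells are untouched
#' and the output contains no missing values, which is what allows a
#' single test sample to be processed exactly like a batch.
#'
#' @param x a [feature_matrix()] or a single sample as a numeric vector in
#'   model feature order.
#' @param model a `mice_model` from [fit_mice()].
#' @return the completed matrix or vector.
#' @export
impute <- function(x, model) {
  single <- is.numeric(x) && is.null(dim(x))
  if (single) {
    vals <- matrix(x, 1, dimnames = list(NULL, names(x)))
  } else {
    if (!identical(x$features$metabolite_id, model$feature_order)) {
      .fail("feature order does not match the imputation model")
    }
    vals <- x$values
  }
  if (ncol(vals) != length(model$feature_order)) {
    .fail("sample length does not match the imputation model")
  }
  n_pass <- max(1L, model$n_iterations_run)
  for (s in seq_len(nrow(vals))) {
    v <- vals[s, ]
    mis <- which(is.na(v))
    if (length(mis) == 0) next
    if (length(mis) == length(v)) {
      .fail("sample ", s, " is entirely missing; cannot impute")
    }
    v[mis] <- model$feature_means[mis]
    order_mis <- model$visit_priority[model$visit_priority %in% mis]
    for (pass in seq_len(n_pass)) {
      for (j in order_mis) {
        pj <- model$pred_idx[[j]]
        v[j] <- model$regressor$predict(
          model$regressors[[j]], matrix(v[pj], 1))
      }
    }
    vals[s, ] <- v
  }
  if (single) return(stats::setNames(vals[1, ], names(x)))
  x$values <- vals
  .log_transform(x, "mice_imputed(frozen)")
}

#' Serialize / load a MICE model as a directory bundle
#'
#' Writes `manifest.json` (means, predictor indices, visit order,
#' iteration count, regressor spec) plus one regressor artifact per
#' feature.
#'
#' @param model a `mice_model`.
#' @param dir bundle directory (created if needed).
#' @return `read_mice_model()` returns the model (with the default
#'   [xgb_regressor()] backend).
#' @export
write_mice_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(feature_means = model$feature_means,
                   pred_idx = model$pred_idx,
                   visit_priority = model$visit_priority,
                   feature_order = model$feature_order,
                   n_iterations_run = model$n_iterations_run,
                   max_iterations = model$max_iterations,
                   ssd_trace = model$ssd_trace, seed = model$seed,
                   regressor = model$regressor$spec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  for (j in seq_along(model$regressors)) {
    model$regressor$save(model$regressors[[j]],
                         file.path(dir, sprintf("reg_%05d.json", j)))
  }
  invisible(dir)
}

#' @rdname write_mice_model
#' @export
read_mice_model <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  reg <- do.call(xgb_regressor, m$regressor[c("nrounds", "max_depth",
                                              "eta")])
  p <- length(m$feature_order)
  regs <- lapply(seq_len(p), function(j) {
    reg$load(file.path(dir, sprintf("reg_%05d.json", j)))
  })
  # equal-length index lists come back simplified to a matrix
  pred_idx <- if (is.matrix(m$pred_idx)) {
    lapply(seq_len(nrow(m$pred_idx)), function(i) {
      as.integer(m$pred_idx[i, ])
    })
  } else {
    lapply(m$pred_idx, as.integer)
  }
  structure(list(
    feature_means = stats::setNames(as.numeric(m$feature_means),
                                    m$feature_order),
    regressors = regs, pred_idx = pred_idx,
    visit_priority = as.integer(m$visit_priority),
    feature_order = as.character(m$feature_order),
    n_iterations_run = as.integer(m$n_iterations_run),
    max_iterations = as.integer(m$max_iterations),
    ssd_trace = as.numeric(m$ssd_trace), seed = m$seed,
    regressor = reg), class = "mice_model")
}
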