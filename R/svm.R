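#' Gaussian (RBF) kernel
#'
#' `k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))`, the similarity the
#' classifier uses to project samples into its feature space. Symmetric in
#' its arguments, equal to 1 at `x = x'`, and in `(0, 1]` everywhere.
#'
#' @param x,x_prime equal-length complete numeric vectors.
#' @param sigma kernel width (> 0).
#' @return similarity in `(0, 1]`.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), sigma = 1)  # exp(-1)
#' @export
rbf_kernel <- function(x, x_prime, sigma) {
  if (sigma <= 0) .fail("`sigma` must be positive")
  if (length(x) != length(x_prime)) .fail("vectors differ in length")
  exp(-sum((x - x_prime)^2) / (2 * sigma^2))
}

# pairwise squared Euclidean distances between rows of A and rows of B
.sqdist <- function(A, B = A) {
  ra <- rowSums(A^2); rb <- rowSums(B^2)
  D <- outer(ra, rb, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

.rbf_matrix <- function(A, B, sigma) exp(-.sqdist(A, B) / (2 * sigma^2))

# median pairwise distance heuristic for the kernel width
.sigma_heuristic <- function(X) {
  n <- nrow(X)
  idx <- if (n > 300) sample.int(n, 300) else seq_len(n)
  D <- sqrt(.sqdist(X[idx, , drop = FALSE]))
  median(D[upper.tri(D)])
}

# coerce labels to +1 (cancer) / -1 (normal)
.encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1))) .fail("numeric labels must be -1/+1")
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("cancer", "normal"))) {
    .fail('labels must be "cancer"/"normal" (or -1/+1)')
  }
  ifelse(labels == "cancer", 1, -1)
}

#' Train a soft-margin RBF-kernel support vector machine
#'
#' Solves the soft-margin dual for the Gaussian kernel with an SMO solver
#' (maximal-violating-pair working-set selection, precomputed kernel).
#' Cancer is encoded as the positive class, so larger decision scores mean
#' more cancer-like. The fitted decision function is
#' `F(x) = sum_i alpha_i y_i k(x, x_i; sigma) + b`.
#'
#' @param x complete numeric matrix, rows = samples.
#' @param labels `"cancer"`/`"normal"` character/factor, or -1/+1 numeric;
#'   both classes must be present.
#' @param C box constraint (regularization bound), default 1.
#' @param sigma kernel width; default is the median pairwise distance
#'   heuristic.
#' @param tol KKT violation tolerance for the solver (default 1e-4).
#' @param max_iter solver iteration cap (default scales with n).
#' @return object of class `svm_rbf` with elements `sv` (support
#'   vectors), `alpha`, `y`, `b`, `sigma`, `C`, `objective` (achieved dual
#'   objective), `n_train`, `feature_names`.
#' @export
svm_rbf <- function(x, labels, C = 1, sigma = NULL, tol = 1e-4,
                    max_iter = 0L) {
  x <- as.matrix(x)
  if (anyNA(x)) .fail("training matrix must be complete (no NA)")
  y <- .encode_labels(labels)
  if (length(unique(y)) < 2) .fail("both classes must be present")
  if (is.null(sigma)) sigma <- .sigma_heuristic(x)
  if (sigma <= 0) .fail("`sigma` must be positive")
  K <- .rbf_matrix(x, x, sigma)
  sol <- .smo_solve(K, y, C, tol, as.integer(max_iter))
  keep <- which(sol$alpha > 1e-10)
  structure(list(sv = x[keep, , drop = FALSE], alpha = sol$alpha[keep],
                 y = y[keep], b = sol$b, sigma = sigma, C = C,
                 objective = sol$objective, gap = sol$gap,
                 iterations = sol$iterations, n_train = nrow(x),
                 feature_names = colnames(x)),
            class = "svm_rbf")
}

#' @export
print.svm_rbf <- function(x, ...) {
  cat("svm_rbf: C =", x$C, ", sigma =", signif(x$sigma, 4), ";",
      length(x$alpha), "support vectors of", x$n_train,
      "training samples\n")
  invisible(x)
}

#' Decision scores and class calls from a fitted SVM
#'
#' `decision_score()` evaluates the decision function
#' `F(x) = sum_i alpha_i y_i k(x, x_i) + b` for one or more samples;
#' `classify_scores()` applies the score cutoff (scores strictly above the
#' cutoff call cancer; a score exactly at the cutoff calls normal).
#'
#' @param model a fitted `svm_rbf`.
#' @param x numeric vector (one sample) or matrix (rows = samples) in the
#'   model's feature space.
#' @return `decision_score()`: numeric y-score(s). `classify_scores()`:
#'   character vector of `"cancer"`/`"normal"`.
#' @export
decision_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != ncol(model$sv)) {
    .fail("sample has ", ncol(x), " features; model expects ",
          ncol(model$sv))
  }
  if (anyNA(x)) .fail("samples must be complete for scoring")
  Kx <- .rbf_matrix(as.matrix(x), model$sv, model$sigma)
  drop(Kx %*% (model$alpha * model$y) + model$b)
}

#' @rdname decision_score
#' @param score numeric y-score(s).
#' @param cutoff decision threshold (default 0).
#' @export
classify_scores <- function(score, cutoff = 0) {
  ifelse(score > cutoff, "cancer", "normal")
}

#' @export
#' @rdname decision_score
#' @param object a fitted `svm_rbf`.
#' @param newdata samples to score.
#' @param type `"score"` for decision values, `"class"` for labels.
#' @param ... ignored.
predict.svm_rbf <- function(object, newdata,
                            type = c("score", "class"), ...) {
  type <- match.arg(type)
  sc <- decision_score(object, newdata)
  if (type == "score") sc else classify_scores(sc)
}

#' Serialize / load an SVM model bundle
#'
#' Manifest JSON (scalar parameters) plus a CSV of support vectors with
#' their weights.
#'
#' @param model a fitted `svm_rbf`.
#' @param dir bundle directory.
#' @return `read_svm_model()` returns the `svm_rbf`.
#' @export
write_svm_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(b = model$b, sigma = model$sigma, C = model$C,
                            objective = model$objective,
                            n_train = model$n_train,
                            feature_names = model$feature_names),
                       file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  sv <- data.frame(alpha = model$alpha, y = model$y, model$sv,
                   check.names = FALSE)
  write.csv(sv, file.path(dir, "support_vectors.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  sv <- read.csv(file.path(dir, "support_vectors.csv"),
                 check.names = FALSE)
  structure(list(sv = as.matrix(sv[, -(1:2), drop = FALSE]),
                 alpha = sv$alpha, y = sv$y, b = m$b, sigma = m$sigma,
                 C = m$C, objective = m$objective, n_train = m$n_train,
                 feature_names = as.character(m$feature_names)),
            class = "svm_rbf")
}
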