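# shared fixture builders; everything is generated in code at test time

make_peak_list <- function(run_id, mz, rt = NULL, intensity = NULL,
                           batch_id = "B01") {
  if (is.null(rt)) rt <- rep(100, length(mz))
  if (is.null(intensity)) intensity <- rep(1000, length(mz))
  ord <- order(mz)
  structure(list(run_id = run_id, batch_id = batch_id,
                 peaks = data.frame(mz = mz[ord], rt = rt[ord],
                                    intensity = intensity[ord])),
            class = "peak_list")
}

# tiny hand-specified library for exact annotation oracles
hand_library <- function(masses, origin = NULL, rt = NULL) {
  n <- length(masses)
  if (is.null(origin)) origin <- rep("human", n)
  if (is.null(rt)) rt <- rep(100, n)
  structure(data.frame(
    metabolite_id = sprintf("MB%05d", seq_len(n)),
    name = sprintf("met_%d", seq_len(n)),
    monoisotopic_mass = masses, origin = origin, nominal_rt = rt,
    base_log_abundance = rep(5, n), stringsAsFactors = FALSE),
    class = c("metabolite_library", "data.frame"))
}

# feature matrix straight from a values matrix (features named f1..fp)
hand_matrix <- function(values, ids = NULL, transform_log = character()) {
  p <- ncol(values)
  if (is.null(ids)) ids <- sprintf("MB%05d", seq_len(p))
  colnames(values) <- ids
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  }
  feature_matrix(values,
                 data.frame(metabolite_id = ids,
                            consensus_mz = seq(100, by = 10, length.out = p),
                            consensus_rt = rep(100, p),
                            stringsAsFactors = FALSE),
                 transform_log)
}

# correlated (single latent factor) complete matrix for imputation tests
correlated_matrix <- function(n = 150, p = 40, seed = 7) {
  set.seed(seed)
  z <- rnorm(n)
  load <- runif(p, 0.6, 1.4)
  x <- outer(z, load) + matrix(rnorm(n * p, sd = 0.3), n, p) + 5
  hand_matrix(x, transform_log = c("log10", "quantile_normalized"))
}

# small well-separated two-class matrix
separable_matrix <- function(n_per_class = 20, p = 5, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p) + gap / 2,
             matrix(rnorm(n_per_class * p), ncol = p) - gap / 2)
  labels <- rep(c("cancer", "normal"), each = n_per_class)
  list(x = x, labels = labels)
}
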