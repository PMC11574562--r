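#' Generate a synthetic annotated metabolite library
#'
#' Builds a mock serum-metabolite reference library standing in for a
#' curated annotation database: each record has a unique id, a
#' monoisotopic mass in a small-molecule window, a nominal retention time,
#' a baseline log10 abundance, and an origin class (`human`, `drug`,
#' `plant`, or `ambiguous`). Masses are spaced at least `min_spacing_ppm`
#' apart in relative terms, so peak annotation within any ppm tolerance
#' below half that spacing is unambiguous by construction.
#'
#' @param n_metabolites number of records (>= 1).
#' @param fraction_nonhuman fraction in `[0, 1)` flagged with a non-human
#'   origin; exactly `round(n_metabolites * fraction_nonhuman)` records are
#'   assigned, cycling through `drug`, `plant`, `ambiguous`.
#' @param seed integer RNG seed; identical calls are byte-identical.
#' @param mass_range monoisotopic mass window in Da (default 70-1200).
#' @param min_spacing_ppm minimum relative spacing between neighbouring
#'   masses, in ppm (default 100).
#' @param rt_range nominal retention-time window in seconds.
#' @param abundance_range baseline log10 intensity window.
#' @return data frame of class `metabolite_library` with columns
#'   `metabolite_id`, `name`, `monoisotopic_mass`, `origin`, `nominal_rt`,
#'   `base_log_abundance`, ordered by mass.
#' @examples
#' lib <- simulate_library(50, fraction_nonhuman = 0.2, seed = 1)
#' table(lib$origin)
#' @export
simulate_library <- function(n_metabolites, fraction_nonhuman = 0.2,
                             seed = 1L, mass_range = c(70, 1200),
                             min_spacing_ppm = 100, rt_range = c(30, 900),
                             abundance_range = c(3.5, 7)) {
  if (!is.numeric(n_metabolites) || length(n_metabolites) != 1 ||
      n_metabolites < 1) {
    .fail("`n_metabolites` must be a positive count")
  }
  if (fraction_nonhuman < 0 || fraction_nonhuman >= 1) {
    .fail("`fraction_nonhuman` must lie in [0, 1)")
  }
  n_metabolites <- as.integer(n_metabolites)
  set.seed(seed)

  # draw on log-mass so ppm spacing is a constant gap; greedy thinning
  lo <- log(mass_range[1]); hi <- log(mass_range[2])
  gap <- min_spacing_ppm * 1e-6
  masses <- numeric(0)
  tries <- 0L
  while (length(masses) < n_metabolites) {
    cand <- sort(c(masses, runif(2L * n_metabolites, lo, hi)))
    keep <- c(TRUE, diff(cand) > gap)
    masses <- cand[keep]
    tries <- tries + 1L
    if (tries > 50L) .fail("mass window too crowded for requested spacing")
  }
  masses <- sort(sample(masses, n_metabolites))
  masses <- exp(masses)

  n_nonhuman <- as.integer(round(n_metabolites * fraction_nonhuman))
  origin <- rep("human", n_metabolites)
  if (n_nonhuman > 0) {
    idx <- sample.int(n_metabolites, n_nonhuman)
    origin[idx] <- rep(c("drug", "plant", "ambiguous"),
                       length.out = n_nonhuman)
  }

  lib <- data.frame(
    metabolite_id      = sprintf("MB%05d", seq_len(n_metabolites)),
    name               = sprintf("metabolite_%04d", seq_len(n_metabolites)),
    monoisotopic_mass  = masses,
    origin             = origin,
    nominal_rt         = runif(n_metabolites, rt_range[1], rt_range[2]),
    base_log_abundance = runif(n_metabolites, abundance_range[1],
                               abundance_range[2]),
    stringsAsFactors   = FALSE
  )
  class(lib) <- c("metabolite_library", "data.frame")
  lib
}

# proton mass: neutral monoisotopic mass -> [M+H]+ m/z in positive ion mode
PROTON_MASS <- 1.00727646

#' Read / write the library TSV dialect
#'
#' @param lib a `metabolite_library` data frame.
#' @param path file path of a tab-separated library table.
#' @return `read_library()` returns a `metabolite_library` data frame.
#' @export
write_library <- function(lib, path) {
  utils::write.table(lib, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  class(lib) <- c("metabolite_library", "data.frame")
  lib
}
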