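#' Simulate an observed SFS under the Poisson random field model
#'
#' Class counts are drawn as independent Poisson variables with means
#' proportional to the expected spectrum, after applying the ancestral
#' misidentification mixture at rate `epsilon` (the Poisson-thinning
#' equivalent of flipping each site's class `i -> n - i` with probability
#' `epsilon`).  Totals therefore vary across replicates, consistent with the
#' independence assumption of the model.
#'
#' @param p Expected normalized spectrum (vector of length `n - 1`, or tibble
#'   with `p`), e.g. from [expected_sfs()] or a cache row.
#' @param n_sites Expected total number of segregating sites.
#' @param epsilon Ancestral misidentification rate.
#' @param seed Random seed (required).
#' @return A tibble with columns `i`, `count`, attributes `n` and `seed`.
#' @export
simulate_observed_sfs <- function(p, n_sites, epsilon = 0, seed) {
  if (missing(seed)) abort("a seed is required")
  check_epsilon(epsilon)
  if (n_sites <= 0) abort("n_sites must be > 0")
  pv <- if (is.data.frame(p)) p$p else p
  if (abs(sum(pv) - 1) > 1e-6) abort("p must be a normalized spectrum")
  set.seed(seed)
  mixed <- mixture_spectrum(pv, epsilon)
  counts <- rpois(length(pv), n_sites * mixed)
  out <- tibble::tibble(i = seq_along(pv), count = counts)
  attr(out, "n") <- length(pv) + 1L
  attr(out, "seed") <- seed
  out
}

#' Specification for simulating a scored site table
#'
#' Defines the generative model for a synthetic dataset: a per-bin truth
#' table (bin center, true selection coefficient, expected number of sites),
#' the demography through a spectra cache, the sample size, and the
#' misidentification rate.
#'
#' @param bins A tibble with columns `bin` (score bin center), `s_true`
#'   (true coefficient, <= 0) and `n_sites` (expected sites per bin, > 0).
#' @param cache A [precompute_spectra()] cache whose grid contains every
#'   `s_true`.
#' @param epsilon Misidentification rate in `[0, 1]`.
#' @param scheme A [score_binning()]; simulated scores are jittered uniformly
#'   within each bin so that binning round-trips exactly.
#' @param categories Optional tibble with columns `category` and `prob`
#'   giving per-site category label probabilities (identical across bins).
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(bins, cache, epsilon = 0,
                            scheme = score_binning("integer"),
                            categories = NULL) {
  stopifnot(inherits(cache, "spectra_cache"), inherits(scheme, "score_binning"))
  check_epsilon(epsilon)
  if (!all(c("bin", "s_true", "n_sites") %in% names(bins))) {
    abort("bins must have columns bin, s_true, n_sites")
  }
  if (any(bins$n_sites <= 0)) abort("n_sites must be > 0 in every bin")
  if (any(bins$s_true > 0)) abort("s_true must be <= 0")
  for (s in bins$s_true) cache_row(cache, s)  # errors if truth off the grid
  if (!is.null(categories)) {
    if (!all(c("category", "prob") %in% names(categories)) ||
        abs(sum(categories$prob) - 1) > 1e-9) {
      abort("categories must have columns category, prob with probs summing to 1")
    }
  }
  structure(list(bins = tibble::as_tibble(bins), cache = cache,
                 epsilon = epsilon, scheme = scheme, categories = categories),
            class = "simulation_spec")
}

#' Simulate a scored site table
#'
#' For each bin of the specification, draws an observed SFS via
#' [simulate_observed_sfs()] and emits one record per site with a score
#' placed at the bin center plus a uniform jitter small enough that binning
#' recovers the bin exactly.  Optional category labels are sampled per site.
#'
#' @param spec A [simulation_spec()].
#' @param seed Random seed (required; all randomness flows from it).
#' @return A site table: tibble with columns `chrom`, `pos`, `i`, `n`,
#'   `score`, `category`, and attributes `seed` and `spec`.
#' @export
simulate_scored_sites <- function(spec, seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (missing(seed)) abort("a seed is required")
  set.seed(seed)
  n <- spec$cache$n
  half <- spec$scheme$width / 2 * 0.999
  tabs <- purrr::pmap(spec$bins[c("bin", "s_true", "n_sites")],
                      function(bin, s_true, n_sites) {
    p <- spec$cache$P[cache_row(spec$cache, s_true), ]
    mixed <- mixture_spectrum(p, spec$epsilon)
    counts <- rpois(n - 1, n_sites * mixed)
    i_vals <- rep(seq_len(n - 1), counts)
    m <- length(i_vals)
    if (m == 0) return(NULL)
    tibble::tibble(i = i_vals, n = n,
                   score = bin + runif(m, -half, half))
  })
  out <- dplyr::bind_rows(tabs)
  if (nrow(out) == 0) abort("simulation produced no sites; increase n_sites")
  out <- out[sample.int(nrow(out)), ]
  out$chrom <- "chr1"
  out$pos <- seq_len(nrow(out))
  if (!is.null(spec$categories)) {
    out$category <- sample(spec$categories$category, nrow(out), replace = TRUE,
                           prob = spec$categories$prob)
  } else {
    out$category <- NA_character_
  }
  out <- out[, c("chrom", "pos", "i", "n", "score", "category")]
  attr(out, "seed") <- seed
  attr(out, "sim_epsilon") <- spec$epsilon
  out
}
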