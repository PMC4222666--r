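#' Distributions of fitness effects (DFE) over selection coefficients
#'
#' Two families are supported for per-bin fits: a point mass at a single
#' coefficient `s0 <= 0`, and a gamma distribution over the magnitude
#' \eqn{|s|} with shape `shape` and rate `rate` (mean `shape/rate`, standard
#' deviation `sqrt(shape)/rate`; the ratio mean/SD equals `sqrt(shape)` and
#' summarizes the shape: L-shaped below 1, peaked above 1).
#'
#' @param s0 Selection coefficient of the point mass (<= 0).
#' @return An object of class `dfe_point` or `dfe_gamma`.
#' @export
dfe_point <- function(s0) {
  if (!is.numeric(s0) || length(s0) != 1 || s0 > 0) abort("s0 must be <= 0")
  structure(list(s0 = s0), class = "dfe_point")
}

#' @rdname dfe_point
#' @param shape,rate Gamma shape and rate parameters (> 0) over `|s|`.
#' @export
dfe_gamma <- function(shape, rate) {
  if (!is.numeric(shape) || shape <= 0 || !is.numeric(rate) || rate <= 0) {
    abort("shape and rate must be > 0")
  }
  structure(list(shape = shape, rate = rate), class = "dfe_gamma")
}

#' Density of a gamma DFE at given selection coefficients
#'
#' @param dfe A [dfe_gamma()].
#' @param s Selection coefficients (the density is over the magnitude, so
#'   `s = -1e-4` and `1e-4` give the same value).
#' @return Density values.
#' @export
dfe_density <- function(dfe, s) UseMethod("dfe_density")

#' @export
dfe_density.dfe_gamma <- function(dfe, s) dgamma(abs(s), dfe$shape, rate = dfe$rate)

#' @export
dfe_density.dfe_point <- function(dfe, s) {
  abort("a point mass has no density; use the spectrum at s0 directly")
}

#' @export
print.dfe_gamma <- function(x, ...) {
  cat(sprintf("<dfe_gamma> shape = %g, rate = %g (mean |s| = %g, SD = %g)\n",
              x$shape, x$rate, x$shape / x$rate, sqrt(x$shape) / x$rate))
  invisible(x)
}

#' @export
print.dfe_point <- function(x, ...) {
  cat(sprintf("<dfe_point> s0 = %g\n", x$s0))
  invisible(x)
}

#' Default selection-coefficient fitting grid
#'
#' Grid of `s = 0` plus negative coefficients log-spaced in magnitude:
#' `log10(|s|)` from `log10_min` to `log10_max` in steps of `step`.
#' Defaults give 801 points from 1e-6 to 1e-2.
#'
#' @param log10_min,log10_max Range of `log10(|s|)`.
#' @param step Step in `log10(|s|)` units.
#' @return A sorted numeric vector of selection coefficients (ascending, most
#'   negative first, ending at 0).
#' @export
s_grid_default <- function(log10_min = -6, log10_max = -2, step = 0.005) {
  mags <- 10^seq(log10_min, log10_max, by = step)
  c(-rev(mags), 0)
}

#' Precompute expected spectra on a selection-coefficient grid
#'
#' Solving the diffusion once per `(demography, n, s)` and reusing the result
#' across score bins, EM iterations and bootstrap replicates is the central
#' performance device of the fitting pipeline.
#'
#' @param model A [demography_model()].
#' @param n Haploid sample size.
#' @param s_values Selection coefficients (raw `s`, <= 0), e.g.
#'   [s_grid_default()].
#' @param theta Scale factor (irrelevant for shape-only likelihoods).
#' @param control A [solver_control()].
#' @param init Initial condition passed to [solve_population_spectrum()].
#' @return An object of class `spectra_cache` holding the expected (`E`) and
#'   normalized (`P`) spectra, one row per grid coefficient.
#' @export
precompute_spectra <- function(model, n, s_values = s_grid_default(),
                               theta = 1, control = solver_control(),
                               init = "equilibrium") {
  s_values <- sort(unique(s_values))
  if (any(s_values > 0)) abort("s_values must be <= 0")
  E <- matrix(NA_real_, nrow = length(s_values), ncol = n - 1)
  for (k in seq_along(s_values)) {
    pop <- solve_population_spectrum(
      model, S = scale_selection(s_values[k], model$N0), theta = theta,
      control = control, init = init)
    E[k, ] <- sample_spectrum(pop, n)$e
  }
  P <- E / rowSums(E)
  structure(list(s = s_values, E = E, P = P, n = as.integer(n), theta = theta,
                 model = model, model_hash = model_hash(model),
                 control = control),
            class = "spectra_cache")
}

#' @export
print.spectra_cache <- function(x, ...) {
  cat("<spectra_cache>", length(x$s), "selection coefficients, n =", x$n,
      "\n  model:", x$model$label, " hash:", x$model_hash, "\n")
  invisible(x)
}

#' Write/read a spectra cache as TSV
#'
#' Plain-text cache keyed by (model hash, n): header comment lines followed by
#' one row per grid coefficient with the unnormalized expected spectrum.
#'
#' @param cache A `spectra_cache`.
#' @param path File path.
#' @return `write_spectra_cache()` returns `path` invisibly;
#'   `read_spectra_cache()` returns a `spectra_cache` (without the originating
#'   model object, which is recorded only through its hash and label).
#' @export
write_spectra_cache <- function(cache, path) {
  stopifnot(inherits(cache, "spectra_cache"))
  hdr <- c(sprintf("# n\t%d", cache$n),
           sprintf("# theta\t%.17g", cache$theta),
           sprintf("# model_hash\t%s", cache$model_hash),
           sprintf("# model_label\t%s", cache$model$label %||% "unknown"))
  tab <- tibble::as_tibble(cache$E, .name_repair = ~ paste0("e", seq_len(cache$n - 1)))
  tab <- dplyr::bind_cols(tibble::tibble(s = cache$s), tab)
  writeLines(hdr, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_spectra_cache
#' @export
read_spectra_cache <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
  meta <- setNames(kv[, 2], kv[, 1])
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  E <- as.matrix(tab[, -1])
  dimnames(E) <- NULL
  n <- as.integer(meta[["n"]])
  structure(list(s = tab$s, E = E, P = E / rowSums(E), n = n,
                 theta = as.numeric(meta[["theta"]]),
                 model = list(label = meta[["model_label"]]),
                 model_hash = meta[["model_hash"]], control = NULL),
            class = "spectra_cache")
}

# nearest cache row for a point coefficient; error if not on the grid
cache_row <- function(cache, s0, tol = 1e-12) {
  k <- which.min(abs(cache$s - s0))
  if (abs(cache$s[k] - s0) > tol + 1e-9 * abs(s0)) {
    abort(sprintf("s = %g is not on the cached grid", s0))
  }
  k
}

#' Mix cached spectra over a DFE
#'
#' For a gamma DFE the expected spectrum is the trapezoid-rule mixture of the
#' cached per-coefficient spectra weighted by the gamma density over
#' \eqn{|s|}.  Gamma mass below the smallest cached magnitude is effectively
#' neutral and is assigned to the `s = 0` spectrum (or the weakest cached
#' coefficient when the cache lacks a neutral row); mass above the largest
#' cached magnitude must be negligible.
#'
#' @param cache A [precompute_spectra()] result whose grid covers the DFE.
#' @param dfe A [dfe_gamma()] or [dfe_point()].
#' @param coverage_min Minimum gamma mass that must fall at or below the
#'   largest cached magnitude (default 0.999).
#' @return A tibble with columns `i` and `e` (unnormalized mixture).
#' @export
integrate_spectrum_over_dfe <- function(cache, dfe, coverage_min = 0.999) {
  stopifnot(inherits(cache, "spectra_cache"))
  e <- mix_expected(cache, dfe, coverage_min, penalized = FALSE)
  out <- tibble::tibble(i = seq_len(cache$n - 1), e = e)
  attr(out, "n") <- cache$n
  out
}

# core mixing kernel; with penalized = TRUE returns NULL instead of erroring
# when coverage fails (used inside optimization)
mix_expected <- function(cache, dfe, coverage_min = 0.999, penalized = FALSE) {
  if (inherits(dfe, "dfe_point")) {
    return(cache$E[cache_row(cache, dfe$s0), ])
  }
  stopifnot(inherits(dfe, "dfe_gamma"))
  sel <- which(cache$s < 0)
  if (length(sel) < 3) abort("cache needs at least 3 negative grid coefficients")
  m <- -cache$s[sel]
  ord <- order(m)
  m <- m[ord]
  rows <- sel[ord]
  covered <- pgamma(max(m), dfe$shape, rate = dfe$rate)
  if (covered < coverage_min) {
    if (penalized) return(NULL)
    abort(sprintf(
      "s-grid covers only %.4f of the gamma mass (need >= %.4f); extend the grid",
      covered, coverage_min))
  }
  K <- length(m)
  w <- c((m[2] - m[1]) / 2, (m[3:K] - m[1:(K - 2)]) / 2, (m[K] - m[K - 1]) / 2)
  wts <- w * dgamma(m, dfe$shape, rate = dfe$rate)
  lower <- pgamma(min(m), dfe$shape, rate = dfe$rate)
  neutral_row <- if (any(cache$s == 0)) which(cache$s == 0) else rows[1]
  tot <- sum(wts) + lower
  (lower * cache$E[neutral_row, ] + colSums(wts * cache$E[rows, , drop = FALSE])) / tot
}
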