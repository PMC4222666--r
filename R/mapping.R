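#' Score binning schemes
#'
#' Two schemes mirror the two score dialects: `"integer"` rounds scores to
#' the nearest integer (half away from zero) with a maximum admitted score of
#' 40, for natively PHRED-scaled deleteriousness scores; `"quarter"` rounds
#' to the nearest 0.25 units with a maximum of 5, for rank-rescaled scores
#' (see [phred_rescale()]).
#'
#' @param scheme `"integer"` or `"quarter"`.
#' @param max_score Largest admitted bin center (defaults 40 / 5); sites whose
#'   bin exceeds it are excluded and counted.
#' @return A list of class `score_binning` with fields `scheme`, `width`,
#'   `max_score`.
#' @export
score_binning <- function(scheme = c("integer", "quarter"), max_score = NULL) {
  scheme <- match.arg(scheme)
  width <- if (scheme == "integer") 1 else 0.25
  max_score <- max_score %||% if (scheme == "integer") 40 else 5
  structure(list(scheme = scheme, width = width, max_score = max_score),
            class = "score_binning")
}

# round half away from zero to a multiple of `width`
round_half_away <- function(x, width = 1) {
  sign(x) * floor(abs(x) / width + 0.5) * width
}

score_to_bin <- function(score, scheme) round_half_away(score, scheme$width)

#' Bin scored sites and compute the per-bin site frequency spectrum
#'
#' Each admitted site contributes its derived-allele class to exactly one
#' bin's SFS; sites whose rounded score exceeds the scheme's cutoff are
#' excluded and reported via the `n_excluded` attribute.
#'
#' @param sites A site table: tibble with at least columns `i` (derived
#'   count), `n` (haploid sample size, identical across rows) and `score`.
#' @param scheme A [score_binning()].
#' @return A tibble with columns `bin`, `i`, `count` (one row per bin and
#'   frequency class, zero classes included), with attributes `n`,
#'   `n_excluded` and `scheme`.
#' @export
bin_sites_by_score <- function(sites, scheme = score_binning("integer")) {
  stopifnot(inherits(scheme, "score_binning"))
  if (nrow(sites) == 0) abort("empty site table")
  n <- unique(sites$n)
  if (length(n) != 1) abort("all sites must share the same sample size n")
  if (any(sites$i < 1 | sites$i > n - 1)) abort("derived counts must be in 1..n-1")
  bin <- score_to_bin(sites$score, scheme)
  keep <- bin <= scheme$max_score
  tab <- tibble::tibble(bin = bin[keep], i = sites$i[keep]) |>
    dplyr::count(.data$bin, .data$i, name = "count") |>
    tidyr::complete(.data$bin, i = seq_len(n - 1),
                    fill = list(count = 0L)) |>
    dplyr::arrange(.data$bin, .data$i)
  attr(tab, "n") <- as.integer(n)
  attr(tab, "n_excluded") <- sum(!keep)
  attr(tab, "scheme") <- scheme
  tab
}

#' Extract one bin's observed SFS from a binned table
#'
#' @param binned Output of [bin_sites_by_score()].
#' @param bin Bin center.
#' @return A tibble with columns `i`, `count` and attribute `n`.
#' @export
bin_counts <- function(binned, bin) {
  out <- binned[binned$bin == bin, c("i", "count")]
  if (nrow(out) == 0) abort(sprintf("no such bin: %g", bin))
  attr(out, "n") <- attr(binned, "n")
  out
}

#' Rank-based PHRED rescaling of scores
#'
#' Converts each score to \eqn{-\log_{10}(p)}, where `p` is the proportion of
#' sites in the input whose score is as or more extreme (self-inclusive).
#' With the default orientation, larger input scores are more
#' conserved/disruptive.  The minimum score maps to 0 and a unique maximum
#' among `M` sites maps to \eqn{-\log_{10}(1/M)}; ties share identical
#' outputs, and the result is invariant to any strictly increasing transform
#' of the inputs.
#'
#' @param scores Numeric scores.
#' @param higher_is_extreme Orientation: if `TRUE` (default) larger values
#'   are more conserved/disruptive; set `FALSE` for scores where smaller
#'   values are more extreme.
#' @return Rescaled scores (same length).
#' @export
phred_rescale <- function(scores, higher_is_extreme = TRUE) {
  if (length(scores) < 1) abort("at least one score is required")
  if (any(!is.finite(scores))) abort("scores must be finite")
  if (!higher_is_extreme) scores <- -scores
  M <- length(scores)
  n_as_or_more <- M - rank(scores, ties.method = "min") + 1
  -log10(n_as_or_more / M)
}

#' Fit selection models to every score bin
#'
#' Runs [fit_point_selection()] (and optionally [fit_gamma_selection()] with
#' the likelihood-ratio test and a chi-squared goodness-of-fit diagnostic)
#' on each bin of a binned site table, reusing one spectra cache throughout.
#'
#' @param binned Output of [bin_sites_by_score()].
#' @param cache A [precompute_spectra()] cache under the fitted demography.
#' @param fit_gamma Also fit the gamma DFE per bin (default `FALSE`).
#' @param gof Compute the chi-squared diagnostic per bin (default `TRUE`).
#' @param gof_params Parameter count charged to the point model in the GOF
#'   test (default 2: the coefficient and epsilon).
#' @param ... Passed to the per-bin fitters.
#' @return A mapping table: one row per bin with `bin`, `n_sites`, `s_hat`,
#'   `epsilon`, `loglik_point`, `neutral`, `low_data`, plus gamma/LRT/GOF
#'   columns when requested.  Class `mapping_table`.
#' @export
fit_score_bins <- function(binned, cache, fit_gamma = FALSE, gof = TRUE,
                           gof_params = 2, ...) {
  bins <- sort(unique(binned$bin))
  n_tests <- length(bins)
  rows <- purrr::map(bins, function(b) {
    cb <- bin_counts(binned, b)
    pt <- fit_point_selection(cb, cache, ...)
    row <- tibble::tibble(
      bin = b, n_sites = pt$n_sites, s_hat = pt$s_hat, epsilon = pt$epsilon,
      loglik_point = pt$loglik, neutral = pt$s_hat == 0,
      low_data = pt$low_data)
    if (gof && sum(cb$count) > 0) {
      gt <- tryCatch(
        gof_chi_squared(cb, mixture_spectrum(pt$p, pt$epsilon),
                        n_params = gof_params, n_tests = n_tests),
        error = function(e) NULL)
      row$chisq_stat <- if (is.null(gt)) NA_real_ else gt$statistic
      row$chisq_p <- if (is.null(gt)) NA_real_ else gt$p_value
      row$chisq_sig <- if (is.null(gt)) NA else gt$significant
    }
    if (fit_gamma) {
      gm <- fit_gamma_selection(cb, cache, ...)
      lr <- lrt_gamma_vs_point(pt, gm, n_tests = n_tests)
      row$shape <- gm$shape
      row$rate <- gm$rate
      row$loglik_gamma <- gm$loglik
      row$lrt_stat <- lr$statistic
      row$lrt_p <- lr$p_value
      row$lrt_sig <- lr$significant
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n") <- attr(binned, "n")
  attr(out, "scheme") <- attr(binned, "scheme")
  class(out) <- c("mapping_table", class(out))
  out
}

#' Bootstrap confidence intervals for per-bin selection coefficients
#'
#' Resamples the sites within each bin with replacement `B` times, refits the
#' point coefficient per replicate against the cached spectra, and returns
#' the bootstrap SD and percentile 95% interval of `s_hat` per bin.
#'
#' @param binned Output of [bin_sites_by_score()].
#' @param cache Spectra cache.
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Random seed (required for reproducibility).
#' @param level Interval coverage (default 0.95).
#' @param ... Passed to [fit_point_selection()].
#' @return A tibble with `bin`, `boot_sd`, `ci_lo`, `ci_hi`, `B`.
#' @export
bootstrap_mapping <- function(binned, cache, B = 100, seed, level = 0.95,
                              ...) {
  if (B < 2) abort("B must be >= 2")
  if (missing(seed)) abort("a seed is required")
  set.seed(seed)
  bins <- sort(unique(binned$bin))
  alpha <- (1 - level) / 2
  purrr::map_dfr(bins, function(b) {
    cb <- bin_counts(binned, b)
    tot <- sum(cb$count)
    if (tot == 0) {
      return(tibble::tibble(bin = b, boot_sd = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, B = 0L, skipped = TRUE))
    }
    reps <- rmultinom(B, size = tot, prob = cb$count / tot)
    s_rep <- apply(reps, 2, function(cv) {
      fit_point_selection(cv, cache, ...)$s_hat
    })
    tibble::tibble(bin = b, boot_sd = sd(s_rep),
                   ci_lo = unname(stats::quantile(s_rep, alpha)),
                   ci_hi = unname(stats::quantile(s_rep, 1 - alpha)),
                   B = as.integer(B), skipped = FALSE)
  })
}

#' Build the continuous score-to-s mapping
#'
#' Bins whose maximum-likelihood coefficient is exactly 0 are recorded as the
#' neutral score set and excluded; a cubic smoothing spline with (by default)
#' 20 effective degrees of freedom is fitted to `log10(-s_hat)` against the
#' bin center over the remaining bins.  Evaluation clamps scores outside the
#' fitted domain and returns `s = 0` for scores falling in neutral bins.
#'
#' @param bin_fits A [fit_score_bins()] mapping table.
#' @param df Spline effective degrees of freedom (default 20; reduced with a
#'   warning when fewer than `df + 1` non-neutral bins are available).
#' @return An object of class `score_mapping`.
#' @export
build_mapping <- function(bin_fits, df = 20) {
  sel <- !bin_fits$neutral
  if (!any(sel)) abort("all bins are neutral; no mapping can be built")
  x <- bin_fits$bin[sel]
  y <- log10(-bin_fits$s_hat[sel])
  if (length(x) < 4) abort("need at least 4 non-neutral bins for a spline")
  df_use <- df
  if (length(x) < df + 1) {
    df_use <- max(2, length(x) - 1)
    warn(sprintf("only %d non-neutral bins; spline df reduced from %d to %d",
                 length(x), df, df_use))
  }
  sp <- smooth.spline(x, y, df = df_use)
  structure(
    list(spline = sp, neutral_bins = bin_fits$bin[bin_fits$neutral],
         domain = range(x), df = df_use,
         scheme = attr(bin_fits, "scheme") %||% score_binning("integer")),
    class = "score_mapping")
}

#' @export
print.score_mapping <- function(x, ...) {
  cat(sprintf(
    "<score_mapping> spline df = %.1f on [%g, %g]; %d neutral bin(s)\n",
    x$df, x$domain[1], x$domain[2], length(x$neutral_bins)))
  invisible(x)
}

#' Evaluate a score-to-s mapping
#'
#' @param object A [build_mapping()] result.
#' @param scores Scores at which to evaluate.
#' @param ... Unused.
#' @return Selection coefficients: 0 for scores in neutral bins, otherwise
#'   `-10^spline(score)` with the score clamped to the fitted domain.
#' @export
predict.score_mapping <- function(object, scores, ...) {
  bin <- score_to_bin(scores, object$scheme)
  clamped <- pmin(pmax(scores, object$domain[1]), object$domain[2])
  s <- -10^predict(object$spline, clamped)$y
  s[bin %in% object$neutral_bins] <- 0
  s
}

#' @export
tidy.score_mapping <- function(x, ...) {
  grid <- seq(x$domain[1], x$domain[2], length.out = 200)
  tibble::tibble(score = grid, s = predict(x, grid))
}

#' Randomize score labels across sites (null mappings control)
#'
#' Permutes the score column across sites, preserving both the multiset of
#' scores and the multiset of derived counts, so each permuted dataset has
#' the same pooled SFS and the same score histogram as the original.  Used to
#' verify that a fitted mapping is not an artifact of bin occupancy: on
#' permuted labels the rebuilt mapping should be flat.
#'
#' @param sites A site table.
#' @param R Number of replicates (>= 1).
#' @param seed Random seed.
#' @return A list of `R` site tables with permuted `score` columns.
#' @export
randomize_labels <- function(sites, R, seed) {
  if (R < 1) abort("R must be >= 1")
  if (missing(seed)) abort("a seed is required")
  set.seed(seed)
  purrr::map(seq_len(R), function(r) {
    out <- sites
    out$score <- sample(sites$score)
    out
  })
}

#' Refit the mapping table on label-randomized data
#'
#' @inheritParams randomize_labels
#' @param cache Spectra cache.
#' @param scheme A [score_binning()].
#' @param ... Passed to [fit_score_bins()].
#' @return A list of `R` mapping tables.
#' @export
null_mappings <- function(sites, cache, scheme = score_binning("integer"),
                          R = 100, seed, ...) {
  perms <- randomize_labels(sites, R, seed)
  purrr::map(perms, function(p) {
    fit_score_bins(bin_sites_by_score(p, scheme), cache, gof = FALSE, ...)
  })
}

#' Write/read a mapping table TSV
#'
#' @param tab A [fit_score_bins()] mapping table (optionally joined with
#'   bootstrap columns).
#' @param path File path.
#' @export
write_mapping_table <- function(tab, path) {
  readr::write_tsv(tibble::as_tibble(tab), path)
  invisible(path)
}

#' @rdname write_mapping_table
#' @export
read_mapping_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  class(out) <- c("mapping_table", class(out))
  out
}
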