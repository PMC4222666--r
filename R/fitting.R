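#' Candidate demographies for the neutral-bin grid search
#'
#' The constant-size model plus exponential-growth models over a grid of
#' population-scaled growth rates `r` and total growth times `t` (in
#' generations).
#'
#' @param r_values Scaled growth rates (default `c(0.25, 0.5, 1, 2, 4)`).
#' @param t_values Growth durations in generations (default 1000 to 20000 in
#'   steps of 1000).
#' @param N0 Diploid reference population size.
#' @param include_constant Include the constant-size model (default `TRUE`).
#' @return A named list of [demography_model()] objects.
#' @export
demography_grid <- function(r_values = c(0.25, 0.5, 1, 2, 4),
                            t_values = seq(1000, 20000, by = 1000),
                            N0 = 10000, include_constant = TRUE) {
  cand <- list()
  if (include_constant) cand$constant <- demog_constant(N0 = N0)
  for (r in r_values) {
    for (t in t_values) {
      cand[[sprintf("growth r=%g t=%g", r, t)]] <- demog_exponential(r, t, N0 = N0)
    }
  }
  cand
}

#' Fit a demographic model to the neutral-bin SFS
#'
#' Computes the expected neutral (`s = 0`) spectrum for every candidate
#' demography, then runs the EM algorithm in which the model M step is a grid
#' search over candidates and epsilon is re-estimated jointly.
#'
#' @param neutral_sfs Observed SFS of the presumed-neutral (lowest-score) bin:
#'   tibble with columns `i`, `count` (and attribute `n`), or a bare count
#'   vector with `n` implied by its length.
#' @param candidates A named list of [demography_model()] objects, e.g. from
#'   [demography_grid()].
#' @param n Haploid sample size; defaults to the `n` attribute of
#'   `neutral_sfs`.
#' @param control A [solver_control()].
#' @param ... Passed to [run_em()] (`init_epsilon`, `tol`, `max_iter`).
#' @return An object of class `demography_fit`: the best model and its label,
#'   `epsilon`, `loglik`, and `candidate_table` with the per-candidate
#'   log-likelihood at the final epsilon.
#' @export
fit_demography <- function(neutral_sfs, candidates, n = NULL,
                           control = solver_control(), ...) {
  cv <- counts_vec(neutral_sfs)
  n <- n %||% attr(neutral_sfs, "n") %||% (length(cv) + 1L)
  if (length(cv) != n - 1) abort("counts length must be n - 1")
  if (length(candidates) == 0) abort("empty candidate set")
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, function(m) m$label, character(1))
  }

  P <- matrix(NA_real_, nrow = length(candidates), ncol = n - 1)
  ok <- rep(TRUE, length(candidates))
  for (k in seq_along(candidates)) {
    res <- tryCatch(
      expected_sfs(candidates[[k]], n = n, s = 0, control = control)$p,
      error = function(e) NULL)
    if (is.null(res)) ok[k] <- FALSE else P[k, ] <- res
  }
  if (!any(ok)) abort("the solver failed on every candidate demography")
  if (any(!ok)) {
    warn(sprintf("solver failed on %d candidate(s); they were dropped",
                 sum(!ok)))
  }

  P_ok <- P[ok, , drop = FALSE]
  P_ok_rev <- P_ok[, rev(seq_len(ncol(P_ok))), drop = FALSE]
  idx_ok <- which(ok)
  family <- function(counts, epsilon, state) {
    Pm <- (1 - epsilon) * P_ok + epsilon * P_ok_rev
    ll <- as.vector(log(Pm) %*% counts)
    best <- which.max(ll)
    list(p = P_ok[best, ], params = list(index = idx_ok[best]), state = NULL)
  }
  em <- run_em(cv, family, ...)
  best_idx <- em$params$index
  eps <- em$epsilon
  ll_all <- rep(NA_real_, length(candidates))
  for (k in seq_along(candidates)) {
    if (ok[k]) ll_all[k] <- em_loglik(cv, P[k, ], eps)
  }
  structure(
    list(model = candidates[[best_idx]], label = names(candidates)[best_idx],
         epsilon = eps, loglik = em$loglik, p = em$p, em = em, n = n,
         candidate_table = tibble::tibble(
           label = names(candidates), loglik = ll_all, failed = !ok)),
    class = "demography_fit")
}

#' @export
print.demography_fit <- function(x, ...) {
  cat(sprintf("<demography_fit> best: %s  (epsilon = %.4f, loglik = %.3f)\n",
              x$label, x$epsilon, x$loglik))
  invisible(x)
}

#' @export
tidy.demography_fit <- function(x, ...) x$candidate_table

#' @export
glance.demography_fit <- function(x, ...) {
  tibble::tibble(label = x$label, epsilon = x$epsilon, loglik = x$loglik,
                 n_candidates = nrow(x$candidate_table))
}

#' Fit a single (point-mass) selection coefficient to a bin's SFS
#'
#' Grid search over the cached coefficients during the model M step of the EM
#' algorithm; epsilon is re-estimated jointly with the coefficient.  Ties in
#' the grid argmax break toward the weaker (less negative) coefficient, so
#' identical observed spectra always yield identical fits.
#'
#' @param bin_sfs Observed SFS for one score bin (tibble with `i`, `count`, or
#'   a count vector).
#' @param cache A [precompute_spectra()] cache under the fitted demography;
#'   its grid should include `s = 0`.
#' @param low_data_threshold Bins with fewer sites than this are flagged
#'   `low_data` (default 10); the fit is still returned.
#' @param neutral_margin A bin is called selected only when the best negative
#'   coefficient improves the EM-converged log-likelihood over the neutral
#'   (`s = 0`) fit by more than this margin; otherwise the neutral model is
#'   selected and `s_hat = 0`.  The default, `qchisq(0.95, 1) / 2`, is the
#'   5% likelihood-ratio threshold for one extra parameter.  Set to 0 for the
#'   bare grid argmax.
#' @param ... Passed to [run_em()].
#' @return An object of class `selection_fit` with `kind = "point"`:
#'   `s_hat`, `epsilon`, `loglik`, the expected spectrum `p`,
#'   `loglik_neutral` (the neutral-model fit, when the grid contains 0), and
#'   flags.
#' @export
fit_point_selection <- function(bin_sfs, cache, low_data_threshold = 10,
                                neutral_margin = stats::qchisq(0.95, 1) / 2,
                                ...) {
  stopifnot(inherits(cache, "spectra_cache"))
  cv <- counts_vec(bin_sfs)
  if (length(cv) != cache$n - 1) abort("counts length must be n - 1")
  P <- cache$P
  Prev <- P[, rev(seq_len(ncol(P))), drop = FALSE]
  # tie-break toward the weakest coefficient: scan in order of decreasing s
  ord <- order(cache$s, decreasing = TRUE)
  family <- function(counts, epsilon, state) {
    Pm <- (1 - epsilon) * P + epsilon * Prev
    ll <- as.vector(log(Pm) %*% counts)
    best <- ord[which.max(ll[ord])]
    list(p = P[best, ], params = list(s_hat = cache$s[best], index = best),
         state = NULL)
  }
  em <- run_em(cv, family, ...)
  s_hat <- em$params$s_hat
  loglik <- em$loglik
  p <- em$p
  epsilon <- em$epsilon
  ll_neutral <- NA_real_
  if (any(cache$s == 0)) {
    p0 <- P[which(cache$s == 0), ]
    em0 <- run_em(cv, fixed_model_family(p0), ...)
    ll_neutral <- em0$loglik
    if (s_hat != 0 && loglik - ll_neutral <= neutral_margin) {
      s_hat <- 0
      loglik <- em0$loglik
      p <- p0
      epsilon <- em0$epsilon
      em <- em0
    }
  }
  structure(
    list(kind = "point", s_hat = s_hat, epsilon = epsilon,
         loglik = loglik, p = p, em = em, loglik_neutral = ll_neutral,
         n_sites = sum(cv), n = cache$n,
         low_data = sum(cv) < low_data_threshold,
         cache_hash = cache$model_hash),
    class = "selection_fit")
}

#' Fit a gamma DFE to a bin's SFS
#'
#' The model M step maximizes the mixed-spectrum log-likelihood over
#' `(log shape, log rate)` with `L-BFGS-B`, warm-started from the previous
#' iteration; the expected spectrum is the trapezoid-rule gamma mixture of
#' the cached per-coefficient spectra.  Parameter proposals whose gamma mass
#' escapes the top of the cached grid are rejected inside the search.
#'
#' @inheritParams fit_point_selection
#' @param init A [dfe_gamma()] giving starting values (default shape 1, mean
#'   `1e-4`).
#' @param coverage_min Minimum gamma mass the cached grid must cover.
#' @return An object of class `selection_fit` with `kind = "gamma"`:
#'   `shape`, `rate`, `epsilon`, `loglik`, expected `p`, and an
#'   `optim_converged` flag.
#' @export
fit_gamma_selection <- function(bin_sfs, cache,
                                init = dfe_gamma(1, 1e4),
                                coverage_min = 0.999,
                                low_data_threshold = 10, ...) {
  stopifnot(inherits(cache, "spectra_cache"))
  cv <- counts_vec(bin_sfs)
  if (length(cv) != cache$n - 1) abort("counts length must be n - 1")
  opt_ok <- TRUE
  family <- function(counts, epsilon, state) {
    par0 <- state %||% log(c(init$shape, init$rate))
    negll <- function(par) {
      e <- mix_expected(cache, dfe_gamma(exp(par[1]), exp(par[2])),
                        coverage_min, penalized = TRUE)
      if (is.null(e)) return(1e10)
      p <- e / sum(e)
      -em_loglik(counts, p, epsilon)
    }
    opt <- optim(par0, negll, method = "L-BFGS-B",
                 lower = log(c(1e-2, 1e-2)), upper = log(c(1e4, 1e9)),
                 control = list(maxit = 200))
    if (opt$convergence != 0) opt_ok <<- FALSE
    shape <- exp(opt$par[1]); rate <- exp(opt$par[2])
    e <- mix_expected(cache, dfe_gamma(shape, rate), coverage_min,
                      penalized = TRUE)
    if (is.null(e)) abort("gamma mass escapes the cached s-grid at the optimum")
    list(p = e / sum(e), params = list(shape = shape, rate = rate),
         state = opt$par)
  }
  em <- run_em(cv, family, ...)
  structure(
    list(kind = "gamma", shape = em$params$shape, rate = em$params$rate,
         epsilon = em$epsilon, loglik = em$loglik, p = em$p, em = em,
         n_sites = sum(cv), n = cache$n,
         low_data = sum(cv) < low_data_threshold,
         optim_converged = opt_ok, cache_hash = cache$model_hash),
    class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  if (x$kind == "point") {
    cat(sprintf("<selection_fit/point> s_hat = %g, epsilon = %.4f, loglik = %.3f\n",
                x$s_hat, x$epsilon, x$loglik))
  } else {
    cat(sprintf(
      "<selection_fit/gamma> shape = %.3g, rate = %.3g (mean |s| = %.3g), epsilon = %.4f, loglik = %.3f\n",
      x$shape, x$rate, x$shape / x$rate, x$epsilon, x$loglik))
  }
  invisible(x)
}

#' @export
tidy.selection_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    s_hat = if (x$kind == "point") x$s_hat else NA_real_,
    shape = if (x$kind == "gamma") x$shape else NA_real_,
    rate = if (x$kind == "gamma") x$rate else NA_real_,
    mean_s = if (x$kind == "gamma") x$shape / x$rate else abs(x$s_hat),
    epsilon = x$epsilon, loglik = x$loglik, n_sites = x$n_sites,
    low_data = x$low_data)
}

#' @export
glance.selection_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, epsilon = x$epsilon, loglik = x$loglik,
                 n_sites = x$n_sites)
}

#' Likelihood-ratio test of the gamma DFE against the point mass
#'
#' Statistic `2 * (loglik_gamma - loglik_point)`, floored at zero, referred to
#' a chi-squared distribution with 1 degree of freedom (the gamma family adds
#' one parameter; the boundary non-regularity makes this convention
#' conservative).  Significance uses a Bonferroni-corrected level
#' `0.05 / n_tests`.
#'
#' @param point,gamma `selection_fit` objects for the same bin and demography.
#' @param n_tests Number of bins tested (Bonferroni denominator).
#' @return A tibble with `statistic`, `df`, `p_value`, `significant`.
#' @export
lrt_gamma_vs_point <- function(point, gamma, n_tests = 1) {
  stopifnot(inherits(point, "selection_fit"), inherits(gamma, "selection_fit"))
  if (point$kind != "point" || gamma$kind != "gamma") {
    abort("arguments must be a point fit and a gamma fit, in that order")
  }
  if (!identical(point$cache_hash, gamma$cache_hash) ||
      point$n_sites != gamma$n_sites) {
    abort("fits do not come from the same bin and demography")
  }
  stat <- max(0, 2 * (gamma$loglik - point$loglik))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = 1, p_value = p,
                 significant = p < 0.05 / n_tests)
}

#' Pearson chi-squared goodness of fit of a fitted spectrum
#'
#' Classes are pooled from the high-frequency end (merging adjacent classes)
#' until every expected count is at least 5; the statistic is
#' \eqn{\sum (c_i - E_i)^2 / E_i} with `df = classes - n_params - 1`.
#'
#' @param observed Observed SFS (tibble with `i`, `count`, or count vector).
#' @param fitted Fitted class probabilities (tibble with `p`, or vector),
#'   typically the mixed spectrum of a fit (`fit$p` mixed at `fit$epsilon`,
#'   see [mixture_spectrum()]).
#' @param n_params Number of parameters estimated from the data.
#' @param n_tests Bonferroni denominator for the significance call.
#' @param min_expected Pooling threshold (default 5).
#' @return A tibble with `statistic`, `df`, `p_value`, `significant`,
#'   `n_classes` (after pooling).
#' @export
gof_chi_squared <- function(observed, fitted, n_params, n_tests = 1,
                            min_expected = 5) {
  cv <- counts_vec(observed)
  pv <- if (is.data.frame(fitted)) fitted$p else fitted
  if (length(cv) != length(pv)) abort("observed and fitted must align")
  tot <- sum(cv)
  if (tot <= 0) abort("empty SFS")
  E <- pv * tot
  C <- cv
  while (length(E) > 1 && any(E < min_expected)) {
    k <- length(E)
    E <- c(E[seq_len(k - 2)], E[k - 1] + E[k])
    C <- c(C[seq_len(k - 2)], C[k - 1] + C[k])
  }
  df <- length(E) - n_params - 1
  if (df <= 0) abort("not enough classes after pooling for the requested df")
  stat <- sum((C - E)^2 / E)
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 significant = p < 0.05 / n_tests,
                 n_classes = length(E))
}
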