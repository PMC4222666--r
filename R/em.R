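#' Observed-class mixture under ancestral misidentification
#'
#' A site whose ancestral allele is misassigned (probability `epsilon`) has
#' its derived-allele class flipped from `i` to `n - i`, so the observed class
#' probabilities are
#' \eqn{\tilde p_i = (1-\epsilon) p_i + \epsilon p_{n-i}}.
#'
#' @param p Normalized spectrum: numeric vector of length `n - 1`, or a tibble
#'   with columns `i` and `p`.
#' @param epsilon Misidentification rate in `[0, 1]`.
#' @return Same shape as `p`, mixed probabilities (sum to 1).
#' @export
mixture_spectrum <- function(p, epsilon) {
  check_epsilon(epsilon)
  vec <- if (is.data.frame(p)) p$p else p
  mixed <- (1 - epsilon) * vec + epsilon * rev(vec)
  if (is.data.frame(p)) tibble::tibble(i = p$i, p = mixed) else mixed
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon < 0 || epsilon > 1) {
    abort("epsilon must be a single value in [0, 1]")
  }
}

#' E step: posterior probability that a site's ancestral state is misidentified
#'
#' For a site observed at derived-allele class `i`,
#' \eqn{q_i = \epsilon p_{n-i} / ((1-\epsilon) p_i + \epsilon p_{n-i})}.
#'
#' @inheritParams mixture_spectrum
#' @return Posterior probabilities `q_i` in `[0, 1]` (vector or tibble column
#'   `q`, matching the input shape).
#' @export
misid_posterior <- function(p, epsilon) {
  check_epsilon(epsilon)
  vec <- if (is.data.frame(p)) p$p else p
  num <- epsilon * rev(vec)
  den <- (1 - epsilon) * vec + num
  q <- ifelse(den > 0, num / den, 0)
  if (is.data.frame(p)) tibble::tibble(i = p$i, q = q) else q
}

#' M step: re-estimate the misidentification rate
#'
#' \eqn{\epsilon' = \sum_i c_i q_i / \sum_i c_i}: the count-weighted average
#' posterior flip probability.
#'
#' @param counts Observed SFS: numeric vector of class counts, or a tibble
#'   with columns `i` and `count`.
#' @param q Posteriors aligned with `counts` (vector or [misid_posterior()]
#'   tibble).
#' @return Updated epsilon.
#' @export
update_misid_rate <- function(counts, q) {
  cv <- counts_vec(counts)
  qv <- if (is.data.frame(q)) q$q else q
  if (length(cv) != length(qv)) abort("counts and q must align")
  tot <- sum(cv)
  if (tot <= 0) abort("empty SFS")
  sum(cv * qv) / tot
}

counts_vec <- function(counts) {
  if (is.data.frame(counts)) counts$count else counts
}

#' Multinomial log-likelihood of an observed SFS under a mixed spectrum
#'
#' Shape-only likelihood \eqn{\sum_i c_i \log \tilde p_i}, where
#' \eqn{\tilde p} is the misidentification mixture of `p`.  The overall
#' mutation rate is profiled out: only class proportions are fitted.
#'
#' @inheritParams update_misid_rate
#' @param p Normalized spectrum (vector or tibble with `p`).
#' @param epsilon Misidentification rate.
#' @return Log-likelihood (scalar).
#' @export
em_loglik <- function(counts, p, epsilon) {
  cv <- counts_vec(counts)
  pv <- if (is.data.frame(p)) p$p else p
  if (length(cv) != length(pv)) abort("counts and p must align")
  mixed <- (1 - epsilon) * pv + epsilon * rev(pv)
  pos <- cv > 0
  if (any(mixed[pos] <= 0)) abort("zero mixture probability with nonzero count")
  sum(cv[pos] * log(mixed[pos]))
}

#' Run the EM algorithm for ancestral misidentification with model refitting
#'
#' Alternates (1) a model M step that maximizes the observed-data
#' log-likelihood over the model family at the current `epsilon`, (2) the E
#' step computing flip posteriors, and (3) the `epsilon` M step.  Both halves
#' increase the observed-data log-likelihood, so the trace is non-decreasing.
#'
#' @param counts Observed SFS (vector or tibble with `i`, `count`).
#' @param fit_model A callback `function(counts, epsilon, state)` that returns
#'   `list(p = <normalized spectrum vector>, params = <list>, state = <any>)`
#'   maximizing [em_loglik()] over its family for fixed `epsilon`.  `state`
#'   is threaded between iterations for warm starts.
#' @param init_epsilon Starting misidentification rate (default 0.02).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @param fix_epsilon If non-`NULL`, epsilon is held at this value and only
#'   the model is refitted.
#' @return An object of class `em_fit`: `epsilon`, `params`, the fitted
#'   normalized spectrum `p`, flip posteriors `q`, `loglik`, the full
#'   `loglik_trace`, `iterations`, and `converged`/`hit_max_iter` flags.
#' @export
run_em <- function(counts, fit_model, init_epsilon = 0.02, tol = 1e-8,
                   max_iter = 1000, fix_epsilon = NULL) {
  cv <- counts_vec(counts)
  if (sum(cv) <= 0) abort("empty SFS")
  if (tol <= 0) abort("tol must be > 0")
  check_epsilon(init_epsilon)
  eps <- if (is.null(fix_epsilon)) init_epsilon else fix_epsilon
  state <- NULL
  trace <- numeric(0)
  ll_prev <- -Inf
  params <- NULL
  p <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- fit_model(cv, eps, state)
    p <- fit$p
    params <- fit$params
    state <- fit$state
    if (is.null(fix_epsilon)) {
      q <- misid_posterior(p, eps)
      eps <- update_misid_rate(cv, q)
    }
    ll <- em_loglik(cv, p, eps)
    if (is.finite(ll_prev) && ll < ll_prev - (1e-9 + 1e-9 * abs(ll_prev))) {
      abort(sprintf("EM log-likelihood decreased (%.10g -> %.10g)", ll_prev, ll))
    }
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }
  if (!converged) {
    warn(sprintf("EM reached max_iter = %d without converging", max_iter))
  }
  structure(
    list(epsilon = eps, params = params, p = p,
         q = misid_posterior(p, eps), loglik = trace[length(trace)],
         loglik_trace = trace, iterations = length(trace),
         converged = converged, hit_max_iter = !converged),
    class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("<em_fit> epsilon = %.5f, loglik = %.4f, %d iterations%s\n",
              x$epsilon, x$loglik, x$iterations,
              if (x$converged) "" else " (max_iter reached)"))
  invisible(x)
}

#' @export
tidy.em_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$loglik_trace),
                 loglik = x$loglik_trace)
}

#' @export
glance.em_fit <- function(x, ...) {
  tibble::tibble(epsilon = x$epsilon, loglik = x$loglik,
                 iterations = x$iterations, converged = x$converged)
}

# fixed-model callback factory: family with a single known spectrum
fixed_model_family <- function(p) {
  pv <- if (is.data.frame(p)) p$p else p
  function(counts, epsilon, state) list(p = pv, params = list(), state = NULL)
}
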