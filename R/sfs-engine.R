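#' Numerical settings for the diffusion solver
#'
#' @param grid_points Number of frequency grid nodes including the boundaries
#'   0 and 1.  The grid is cosine-clustered, refining resolution near both
#'   boundaries where the spectrum is steep.
#' @param dt Target time step in diffusion time units; each epoch is subdivided
#'   into an integer number of steps no longer than `dt`.
#' @param n_rannacher Number of fully implicit start-up steps used to damp
#'   oscillations from rough initial data before Crank-Nicolson stepping.
#' @param neg_tol Largest tolerated negative density, relative to the maximum
#'   of the solution; beyond it the solver signals instability.
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(grid_points = 2001, dt = 1e-3, n_rannacher = 4,
                           neg_tol = 1e-6) {
  stopifnot(grid_points >= 5, dt > 0, n_rannacher >= 0, neg_tol >= 0)
  structure(list(grid_points = as.integer(grid_points), dt = dt,
                 n_rannacher = as.integer(n_rannacher), neg_tol = neg_tol),
            class = "solver_control")
}

# cosine-clustered grid on [0, 1] including both endpoints
frequency_grid <- function(grid_points) {
  u <- seq(0, 1, length.out = grid_points)
  x <- (1 - cos(pi * u)) / 2
  x[1] <- 0
  x[grid_points] <- 1
  x
}

# Stationary solution of the transformed equation, relative to theta * rho:
#   g(x) / (theta rho) = (e^{2 Sr x} - e^{2 Sr}) / (1 - e^{2 Sr}),  Sr = S * rho
# -> (1 - x) in the neutral limit.  Stable for strongly negative S.
stationary_g_rel <- function(x, Seff) {
  if (abs(Seff) > 1e4) abort("|S| too large for the stationary form (guard at 1e4)")
  if (abs(Seff) < 1e-8) return(1 - x)
  if (Seff < 0) {
    (exp(2 * Seff * x) - exp(2 * Seff)) / (1 - exp(2 * Seff))
  } else {
    expm1(2 * Seff * (x - 1)) / expm1(-2 * Seff)
  }
}

#' Solve the forward diffusion equation for the population frequency spectrum
#'
#' Computes the density \eqn{f(x, \tau)} of segregating sites per unit derived
#' allele frequency at the end of a demographic history, for a single
#' population-scaled selection coefficient \eqn{S = 2 N_0 s} (genic negative
#' selection).  The solved equation is
#' \deqn{\partial_\tau f = \tfrac12 \partial_x^2 [x(1-x) f / \rho(\tau)]
#'       - \partial_x [S\, x(1-x) f]}
#' with mutational influx \eqn{\lim_{x\to 0} x f(x,\tau) = \theta \rho(\tau)}
#' and absorption at \eqn{x = 1}.  Internally the equation is solved for
#' \eqn{g = x(1-x) f}, which obeys simple Dirichlet boundary conditions, by
#' Crank-Nicolson finite differences on a nonuniform grid.
#'
#' @param model A [demography_model()].
#' @param S Population-scaled selection coefficient (\eqn{2 N_0 s}; <= 0 for
#'   negative selection, 0 for neutrality).
#' @param theta Population-scaled mutation rate; a pure scale factor on `f`.
#' @param control A [solver_control()].
#' @param init Initial condition at \eqn{\tau = 0}: `"equilibrium"` (stationary
#'   spectrum at selection `S` and \eqn{\rho = 1}; the default, appropriate
#'   when the history starts from an ancestral equilibrium), `"neutral"`
#'   (neutral stationary spectrum) or `"zero"` (no standing variation).
#' @param check_stationary If `TRUE`, evolve for an additional 0.5 diffusion
#'   time units after the horizon and error if the solution is still changing
#'   by more than 1e-4 (relative); use when an equilibrium answer is expected.
#' @return An object of class `population_spectrum`: interior grid `x`,
#'   density `f`, the transformed solution and grid including boundaries,
#'   `theta`, `S` and the model horizon.
#' @export
solve_population_spectrum <- function(model, S, theta = 1,
                                      control = solver_control(),
                                      init = c("equilibrium", "neutral", "zero"),
                                      check_stationary = FALSE) {
  stopifnot(inherits(model, "demography_model"))
  init <- match.arg(init)
  if (!is.numeric(S) || length(S) != 1 || !is.finite(S)) abort("S must be a finite scalar")
  if (S > 0) abort("positive selection is not supported (S must be <= 0)")
  if (theta <= 0) abort("theta must be > 0")

  x <- frequency_grid(control$grid_points)
  g0 <- switch(init,
    equilibrium = theta * stationary_g_rel(x, S),
    neutral = theta * (1 - x),
    zero = c(theta, rep(0, length(x) - 2), 0))

  ep <- model$epochs
  tau_len <- ep$duration_gen / (2 * model$N0)
  dt_all <- unlist(lapply(tau_len, function(len) {
    ns <- max(1L, ceiling(len / control$dt))
    rep(len / ns, ns)
  }))
  times <- cumsum(c(0, dt_all))
  rho <- relative_size_at(model, pmin(times, model$tau_end))

  g <- cn_evolve_cpp(g0, x, S, theta, rho, dt_all, control$n_rannacher)

  if (check_stationary) {
    n_extra <- max(1L, ceiling(0.5 / control$dt))
    dt_x <- rep(0.5 / n_extra, n_extra)
    rho_end <- rep(rho[length(rho)], n_extra + 1)
    g2 <- cn_evolve_cpp(g, x, S, theta, rho_end, dt_x, 0L)
    resid <- max(abs(g2 - g)) / max(abs(g))
    if (resid > 1e-4) {
      abort(sprintf("solution not stationary at the horizon (residual %.2e)", resid))
    }
    g <- g2
  }

  gmax <- max(abs(g))
  if (min(g) < -control$neg_tol * gmax) {
    abort(sprintf("solver instability: negative density %.2e relative to max",
                  min(g) / gmax))
  }
  g[g < 0] <- 0
  xi <- x[-c(1, length(x))]
  structure(
    list(x = xi, f = g[-c(1, length(x))] / (xi * (1 - xi)),
         x_full = x, g_full = g, theta = theta, S = S,
         tau_end = model$tau_end, model_label = model$label),
    class = "population_spectrum")
}

#' @export
print.population_spectrum <- function(x, ...) {
  cat("<population_spectrum> model:", x$model_label, " S =", x$S,
      " theta =", x$theta, "\n  grid:", length(x$x), "interior points\n")
  invisible(x)
}

#' @export
as_tibble.population_spectrum <- function(x, ...) {
  tibble::tibble(x = x$x, f = x$f)
}

#' Expected sample site frequency spectrum
#'
#' Integrates the population spectrum against the binomial sampling kernel to
#' obtain the expected number of segregating sites \eqn{e_i} with
#' \eqn{i = 1, \dots, n-1} derived copies in a sample of `n` haploid genomes:
#' \deqn{e_{n,i} = \int_0^1 \binom{n}{i} x^i (1-x)^{n-i} f(x)\, dx.}
#' The integral is evaluated by the trapezoid rule on the solver grid (the
#' integrand is finite at both boundaries in the transformed variable).
#'
#' @param pop A `population_spectrum` from [solve_population_spectrum()].
#' @param n Haploid sample size (>= 2).
#' @return A tibble with columns `i` and `e` (length `n - 1`), carrying `n` as
#'   an attribute.
#' @export
sample_spectrum <- function(pop, n) {
  stopifnot(inherits(pop, "population_spectrum"))
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    abort("n must be an integer >= 2")
  }
  x <- pop$x_full
  g <- pop$g_full
  M <- length(x)
  w <- c((x[2] - x[1]) / 2, (x[3:M] - x[1:(M - 2)]) / 2, (x[M] - x[M - 1]) / 2)
  i_vals <- seq_len(n - 1)
  e <- vapply(i_vals, function(i) {
    sum(w * choose(n, i) * x^(i - 1) * (1 - x)^(n - i - 1) * g)
  }, numeric(1))
  out <- tibble::tibble(i = i_vals, e = e)
  attr(out, "n") <- as.integer(n)
  out
}

#' Normalize an expected spectrum to class probabilities
#'
#' @param e A tibble with columns `i` and `e` (as from [sample_spectrum()]),
#'   or a bare numeric vector of expected counts.
#' @return A tibble with columns `i` and `p` summing to 1 (or a numeric vector
#'   when the input was a vector).
#' @export
normalize_spectrum <- function(e) {
  vec <- if (is.data.frame(e)) e$e else e
  tot <- sum(vec)
  if (!is.finite(tot) || tot <= 0) abort("cannot normalize an all-zero spectrum")
  p <- vec / tot
  if (is.data.frame(e)) {
    out <- tibble::tibble(i = e$i, p = p)
    attr(out, "n") <- attr(e, "n")
    out
  } else {
    p
  }
}

#' Stationary sample spectrum by adaptive quadrature (analytic oracle)
#'
#' For a constant-size population the spectrum is available in closed form:
#' \eqn{x(1-x) f(x) = \theta (e^{2Sx} - e^{2S}) / (1 - e^{2S})}, reducing to
#' \eqn{f = \theta / x} at neutrality.  This routine integrates the binomial
#' sampling kernel against that closed form with adaptive quadrature,
#' independently of the finite-difference solver, and is used to validate it.
#'
#' @param S Population-scaled selection coefficient (<= 0; treated as exactly
#'   neutral below |S| = 1e-8, where the two branches agree continuously).
#' @param n Haploid sample size (>= 2).
#' @param theta Population-scaled mutation rate scale factor.
#' @param rel_tol Quadrature relative tolerance.
#' @return A tibble with columns `i` and `e`.
#' @export
equilibrium_sample_spectrum <- function(S, n, theta = 1, rel_tol = 1e-10) {
  if (n < 2 || n != round(n)) abort("n must be an integer >= 2")
  if (S > 0) abort("S must be <= 0")
  i_vals <- seq_len(n - 1)
  e <- vapply(i_vals, function(i) {
    res <- integrate(function(x) {
      choose(n, i) * x^(i - 1) * (1 - x)^(n - i - 1) *
        theta * stationary_g_rel(x, S)
    }, 0, 1, rel.tol = rel_tol, subdivisions = 500L)
    if (res$message != "OK") abort(paste("quadrature failure:", res$message))
    res$value
  }, numeric(1))
  out <- tibble::tibble(i = i_vals, e = e)
  attr(out, "n") <- as.integer(n)
  out
}

#' Population-scaled selection coefficient conversions
#'
#' The internal scaled coefficient is \eqn{S = 2 N_0 s}, matching the
#' diffusion time unit of \eqn{2 N_0} generations.
#'
#' @param s Per-generation selection coefficient(s).
#' @param N0 Diploid reference population size.
#' @return `scale_selection()` returns S; `unscale_selection()` returns s.
#' @export
scale_selection <- function(s, N0 = 10000) 2 * N0 * s

#' @rdname scale_selection
#' @param S Population-scaled coefficient(s).
#' @export
unscale_selection <- function(S, N0 = 10000) S / (2 * N0)

#' Expected normalized sample SFS under a demography and selection coefficient
#'
#' Convenience wrapper: solve the diffusion, sample to `n` haploids and
#' normalize.
#'
#' @inheritParams solve_population_spectrum
#' @param n Haploid sample size.
#' @param s Raw selection coefficient; converted internally via
#'   \eqn{S = 2 N_0 s}.
#' @return A tibble with columns `i`, `e` and `p`.
#' @export
expected_sfs <- function(model, n, s = 0, theta = 1,
                         control = solver_control(),
                         init = "equilibrium") {
  pop <- solve_population_spectrum(model, S = scale_selection(s, model$N0),
                                   theta = theta, control = control, init = init)
  e <- sample_spectrum(pop, n)
  pvec <- normalize_spectrum(e$e)
  out <- tibble::tibble(i = e$i, e = e$e, p = pvec)
  attr(out, "n") <- as.integer(n)
  out
}
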