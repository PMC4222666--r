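#' Population-size histories in diffusion time
#'
#' A demography model is an ordered sequence of epochs describing the relative
#' effective population size \eqn{\rho(\tau)} through time.  Time runs forward:
#' \eqn{\tau = 0} is the most ancient modeled time and \eqn{\tau} increases
#' toward the present.  Diffusion time is measured in units of \eqn{2 N_0}
#' generations, where \eqn{N_0} is the (diploid) reference population size at
#' \eqn{\tau = 0}; by convention \eqn{\rho(0) = 1}.
#'
#' Within a `"constant"` epoch \eqn{\rho} equals the epoch's starting relative
#' size; within an `"exponential"` epoch it grows (or decays) as
#' \eqn{\rho(\tau) = \rho_{start} e^{r (\tau - \tau_{start})}} where `r` is the
#' population-scaled growth rate (per diffusion time unit).  Epochs are
#' right-continuous at breakpoints.
#'
#' @param epochs A data frame with one row per epoch and columns
#'   `duration_gen` (epoch length in generations, > 0), `mode` (`"constant"`
#'   or `"exponential"`), `size_start` (relative size at the epoch start, > 0)
#'   and `rate` (scaled growth rate; ignored for constant epochs).
#' @param N0 Diploid reference population size at time 0 (default 10000).
#' @param label Free-text model label.
#'
#' @return An object of class `demography_model`.
#' @examples
#' m <- demography_model(
#'   tibble::tibble(duration_gen = c(10000, 13000),
#'                  mode = c("constant", "exponential"),
#'                  size_start = c(1, 1), rate = c(0, 1)),
#'   N0 = 10000, label = "burn-in then growth")
#' relative_size_at(m, c(0, 0.5, 1.15))
#' @export
demography_model <- function(epochs, N0 = 10000, label = NULL) {
  epochs <- tibble::as_tibble(epochs)
  req <- c("duration_gen", "mode", "size_start", "rate")
  if (!all(req %in% names(epochs))) {
    abort(paste0("epochs must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(epochs) < 1) abort("at least one epoch is required")
  if (any(epochs$duration_gen <= 0)) abort("epoch durations must be > 0")
  if (any(epochs$size_start <= 0)) abort("relative sizes must be > 0")
  if (!all(epochs$mode %in% c("constant", "exponential"))) {
    abort("epoch mode must be 'constant' or 'exponential'")
  }
  if (!is.numeric(N0) || length(N0) != 1 || N0 <= 0) abort("N0 must be a positive scalar")
  if (abs(epochs$size_start[1] - 1) > 1e-12) {
    abort("the first epoch must start at relative size 1 (rho(0) = 1 convention)")
  }
  epochs$rate[epochs$mode == "constant"] <- 0
  tau_len <- epochs$duration_gen / (2 * N0)
  structure(
    list(epochs = epochs, N0 = N0, label = label %||% "unnamed",
         tau_start = cumsum(c(0, tau_len[-length(tau_len)])),
         tau_end = sum(tau_len)),
    class = "demography_model")
}

#' @export
print.demography_model <- function(x, ...) {
  cat("<demography_model> ", x$label, "\n", sep = "")
  cat("  N0 =", x$N0, " total duration =", format(x$tau_end, digits = 6),
      "diffusion time units (", sum(x$epochs$duration_gen), "generations )\n")
  print(x$epochs)
  invisible(x)
}

#' Constant-size demography
#'
#' @param N0 Diploid reference population size.
#' @param duration_gen Nominal model horizon in generations (the spectrum under
#'   a constant model is stationary, so the horizon only matters when evolving
#'   from non-equilibrium initial conditions).
#' @return A `demography_model`.
#' @export
demog_constant <- function(N0 = 10000, duration_gen = 2 * N0) {
  demography_model(
    tibble::tibble(duration_gen = duration_gen, mode = "constant",
                   size_start = 1, rate = 0),
    N0 = N0, label = "constant")
}

#' Exponential-growth demography
#'
#' Ancestral equilibrium at relative size 1 followed by exponential growth at
#' population-scaled rate `r` for `t_gen` generations, ending at the present.
#'
#' @param r Population-scaled growth rate (per diffusion time unit of
#'   \eqn{2 N_0} generations).
#' @param t_gen Total time of exponential growth, in generations.
#' @param N0 Diploid reference population size.
#' @return A `demography_model`.
#' @export
demog_exponential <- function(r, t_gen, N0 = 10000) {
  demography_model(
    tibble::tibble(duration_gen = t_gen, mode = "exponential",
                   size_start = 1, rate = r),
    N0 = N0, label = sprintf("exponential r=%g t=%g", r, t_gen))
}

#' Relative population size at a diffusion time
#'
#' @param model A `demography_model`.
#' @param tau Diffusion times in `[0, total duration]` (vectorized).
#' @return Numeric vector \eqn{\rho(\tau)}.
#' @export
relative_size_at <- function(model, tau) {
  stopifnot(inherits(model, "demography_model"))
  if (any(tau < -1e-12 | tau > model$tau_end + 1e-12)) {
    abort("tau outside the model horizon [0, total duration]")
  }
  tau <- pmin(pmax(tau, 0), model$tau_end)
  idx <- pmin(findInterval(tau, model$tau_start), nrow(model$epochs))
  ep <- model$epochs
  rho <- ep$size_start[idx] *
    ifelse(ep$mode[idx] == "exponential",
           exp(ep$rate[idx] * (tau - model$tau_start[idx])), 1)
  rho
}

#' Convert generations to diffusion time (and back)
#'
#' Diffusion time is `t / (2 * N0)`; the conversion is exact and round-trips
#' to machine precision.
#'
#' @param model A `demography_model` (supplies `N0`).
#' @param t Times in generations (>= 0).
#' @return Diffusion times.
#' @export
generations_to_diffusion_time <- function(model, t) {
  stopifnot(inherits(model, "demography_model"))
  if (any(t < 0)) abort("t must be >= 0")
  t / (2 * model$N0)
}

#' @rdname generations_to_diffusion_time
#' @param tau Diffusion times (>= 0).
#' @export
diffusion_time_to_generations <- function(model, tau) {
  stopifnot(inherits(model, "demography_model"))
  if (any(tau < 0)) abort("tau must be >= 0")
  tau * 2 * model$N0
}

#' Read and write demography model configuration files
#'
#' The configuration is a YAML file with keys `reference_size`, `label` and an
#' ordered `epochs` list, each epoch carrying `duration_generations`, `mode`,
#' `size_start_relative` and `rate_scaled`.  Writing then reading reproduces
#' the model (rho agrees everywhere to within floating-point round-off).
#'
#' @param path File path.
#' @return `read_demography()` returns a `demography_model`;
#'   `write_demography()` returns `path` invisibly.
#' @export
read_demography <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$reference_size) || is.null(cfg$epochs)) {
    abort("demography config must contain 'reference_size' and 'epochs'")
  }
  ep <- purrr::map_dfr(cfg$epochs, function(e) {
    tibble::tibble(duration_gen = as.numeric(e$duration_generations),
                   mode = as.character(e$mode),
                   size_start = as.numeric(e$size_start_relative),
                   rate = as.numeric(e$rate_scaled %||% 0))
  })
  demography_model(ep, N0 = as.numeric(cfg$reference_size),
                   label = cfg$label %||% basename(path))
}

#' @rdname read_demography
#' @param model A `demography_model`.
#' @export
write_demography <- function(model, path) {
  stopifnot(inherits(model, "demography_model"))
  cfg <- list(
    reference_size = model$N0,
    label = model$label,
    epochs = purrr::pmap(model$epochs, function(duration_gen, mode, size_start, rate) {
      list(duration_generations = duration_gen, mode = mode,
           size_start_relative = size_start, rate_scaled = rate)
    }))
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

model_hash <- function(model) {
  rlang::hash(list(model$N0, model$epochs$duration_gen, model$epochs$mode,
                   model$epochs$size_start, model$epochs$rate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
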