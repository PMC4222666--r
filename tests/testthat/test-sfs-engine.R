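# long-horizon constant model used to test relaxation to stationarity
relax_model <- function(tau = 12) {
  demography_model(tibble::tibble(duration_gen = tau * 2e4, mode = "constant",
                                  size_start = 1, rate = 0))
}

test_that("quadrature oracle reproduces the neutral closed form e_i = theta/i", {
  e <- equilibrium_sample_spectrum(0, n = 18, theta = 3)
  expect_equal(e$e, 3 / (1:17), tolerance = 1e-8)
  # continuity at S = 0 (removable singularity)
  e_eps <- equilibrium_sample_spectrum(-1e-9, n = 18)
  e0 <- equilibrium_sample_spectrum(0, n = 18)
  expect_equal(e_eps$e, e0$e, tolerance = 1e-6)
})

test_that("neutral constant model n = 4 gives p = (6, 3, 2)/11", {
  p <- normalize_spectrum(equilibrium_sample_spectrum(0, n = 4))
  expect_equal(p$p, c(6, 3, 2) / 11, tolerance = 1e-8)
})

test_that("PDE relaxes from empty to the neutral 1/x stationary spectrum", {
  ctl <- solver_control(grid_points = 801, dt = 2e-3)
  pop <- solve_population_spectrum(relax_model(), S = 0, control = ctl,
                                   init = "zero")
  # f * x should equal theta = 1 at every interior point
  expect_lt(max(abs(pop$f * pop$x - 1)), 5e-3)
  e <- sample_spectrum(pop, 18)
  expect_equal(e$e[1] / e$e[2], 2, tolerance = 5e-3)
})

test_that("PDE matches the quadrature oracle under selection (constant model)", {
  ctl <- solver_control(grid_points = 801, dt = 2e-3)
  for (S in c(-1, -10)) {
    pop <- solve_population_spectrum(relax_model(), S = S, control = ctl,
                                     init = "neutral")
    e_pde <- sample_spectrum(pop, 18)$e
    e_or <- equilibrium_sample_spectrum(S, 18)$e
    expect_lt(max(abs(e_pde / e_or - 1)), 0.01)
  }
})

test_that("the stationary spectrum is a fixed point of the evolution", {
  pop <- solve_population_spectrum(demog_constant(), S = -2,
                                   control = ctl_test, init = "equilibrium",
                                   check_stationary = TRUE)
  g_exact <- stationary_g_rel(pop$x_full, -2)
  expect_lt(max(abs(pop$g_full - g_exact)), 2e-4)
})

test_that("spectra are linear in theta and spectra shapes invariant to it", {
  pop1 <- solve_population_spectrum(demog_constant(), S = -1,
                                    control = ctl_test, theta = 1)
  pop2 <- solve_population_spectrum(demog_constant(), S = -1,
                                    control = ctl_test, theta = 2)
  e1 <- sample_spectrum(pop1, 10)$e
  e2 <- sample_spectrum(pop2, 10)$e
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
  expect_equal(normalize_spectrum(e2), normalize_spectrum(e1),
               tolerance = 1e-12)
})

test_that("singleton proportion grows toward 1 with stronger negative selection", {
  p1 <- vapply(c(0, -1, -5, -20, -100), function(S) {
    e <- equilibrium_sample_spectrum(S, 18)$e
    e[1] / sum(e)
  }, numeric(1))
  expect_true(all(diff(p1) > 0))
  expect_gt(p1[length(p1)], 0.9)
})

test_that("exponential growth inflates the neutral singleton class", {
  p_growth <- expected_sfs(growth_model(), 18, s = 0, control = ctl_test)$p
  p_const <- expected_sfs(demog_constant(), 18, s = 0, control = ctl_test)$p
  expect_gt(p_growth[1], p_const[1])
})

test_that("normalization behaves and rejects degenerate input", {
  expect_equal(normalize_spectrum(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(normalize_spectrum(c(2, 1, 1) * 37.5),
               normalize_spectrum(c(2, 1, 1)))
  tab <- tibble::tibble(i = 1:3, e = c(2, 1, 1))
  expect_equal(normalize_spectrum(tab)$p, c(0.5, 0.25, 0.25))
  expect_error(normalize_spectrum(c(0, 0, 0)), "all-zero")
})

test_that("domain errors are raised for invalid solver inputs", {
  pop <- solve_population_spectrum(demog_constant(), S = 0, control = ctl_test)
  expect_error(sample_spectrum(pop, 1), "n must be")
  expect_error(solve_population_spectrum(demog_constant(), S = 1,
                                         control = ctl_test), "positive selection")
  expect_error(equilibrium_sample_spectrum(-1, 1), "n must be")
})
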