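test_that("point-selection fits recover grid truth from expectation counts", {
  cache <- growth_cache()
  for (s_true in snap_to_grid(cache, c(0, -1e-5, -1e-4, -1e-3))) {
    p <- cache$P[cache_row(cache, s_true), ]
    counts <- 1e6 * mixture_spectrum(p, 0.02)
    fit <- fit_point_selection(counts, cache)
    expect_equal(fit$s_hat, s_true)
    expect_lt(abs(fit$epsilon - 0.02), 1e-3)
  }
})

test_that("a neutrally simulated bin maps to s = 0", {
  cache <- growth_cache()
  sim <- simulate_observed_sfs(cache$P[cache_row(cache, 0), ], 1e5,
                               epsilon = 0, seed = 21)
  fit <- fit_point_selection(sim, cache)
  expect_identical(fit$s_hat, 0)
})

test_that("fits are deterministic and self-consistent", {
  cache <- growth_cache()
  sim <- simulate_observed_sfs(cache$P[cache_row(cache, -1e-4), ], 5e4,
                               epsilon = 0.02, seed = 31)
  f1 <- fit_point_selection(sim, cache)
  f2 <- fit_point_selection(sim, cache)
  expect_identical(f1$s_hat, f2$s_hat)
  expect_identical(f1$epsilon, f2$epsilon)
  # reported loglik equals an independent recomputation from (p, epsilon)
  expect_equal(f1$loglik, em_loglik(sim, f1$p, f1$epsilon), tolerance = 1e-12)
  # exhaustive rescan of cached logliks at the final epsilon reproduces s_hat
  ll <- apply(cache$P, 1, function(p) em_loglik(sim, p, f1$epsilon))
  expect_equal(cache$s[which.max(ll)], f1$s_hat)
  # low-data flag
  tiny <- fit_point_selection(c(3, 1, rep(0, 15)), cache)
  expect_true(tiny$low_data)
})

test_that("gamma fits recover the mean of a gamma DFE", {
  cache <- growth_cache()
  truth <- dfe_gamma(2, 2 / 1e-4)
  e <- integrate_spectrum_over_dfe(cache, truth)$e
  sim <- simulate_observed_sfs(e / sum(e), 1e5, epsilon = 0.02, seed = 41)
  fit <- fit_gamma_selection(sim, cache)
  expect_lt(abs(fit$shape / fit$rate - 1e-4) / 1e-4, 0.3)
  expect_true(fit$optim_converged)
})

test_that("the gamma family nests the point fit up to optimizer tolerance", {
  cache <- growth_cache()
  p <- cache$P[cache_row(cache, -1e-4), ]
  counts <- 1e5 * mixture_spectrum(p, 0.02)
  pt <- fit_point_selection(counts, cache)
  gm <- fit_gamma_selection(counts, cache)
  expect_gte(gm$loglik, pt$loglik - 0.5)
})

test_that("the gamma-vs-point LRT follows the chi-squared(1) reference", {
  cache <- growth_cache()
  sim <- simulate_observed_sfs(cache$P[cache_row(cache, -1e-4), ], 2e4,
                               epsilon = 0.02, seed = 51)
  pt <- fit_point_selection(sim, cache)
  gm <- fit_gamma_selection(sim, cache)
  lr <- lrt_gamma_vs_point(pt, gm, n_tests = 40)
  expect_gte(lr$statistic, 0)
  expect_true(lr$p_value >= 0 && lr$p_value <= 1)
  expect_equal(lr$statistic, max(0, 2 * (gm$loglik - pt$loglik)))
  # chi-squared tail arithmetic: a loglik gap of 10 gives statistic 20
  gm2 <- gm; gm2$loglik <- pt$loglik + 10
  lr2 <- lrt_gamma_vs_point(pt, gm2, n_tests = 1)
  expect_equal(lr2$statistic, 20)
  expect_lt(lr2$p_value, 1e-5)
  # mismatched bins are refused
  gm3 <- gm; gm3$n_sites <- gm$n_sites + 1
  expect_error(lrt_gamma_vs_point(pt, gm3), "same bin")
})

test_that("the chi-squared GOF statistic, pooling and df behave", {
  # hand example: c = (12, 8) against E = (10, 10)
  out <- gof_chi_squared(c(12, 8), c(0.5, 0.5), n_params = 0)
  expect_equal(out$statistic, 0.8)
  expect_equal(out$df, 1)
  # perfect fit gives statistic 0
  expect_equal(gof_chi_squared(c(50, 30, 20), c(0.5, 0.3, 0.2),
                               n_params = 0)$statistic, 0)
  # sparse tail classes are pooled from the high-frequency end
  p <- c(0.5, 0.3, 0.1, 0.06, 0.02, 0.01, 0.005, 0.005)
  cts <- round(100 * p)
  out2 <- gof_chi_squared(cts, p, n_params = 0)
  expect_lt(out2$n_classes, length(p))
  expect_error(gof_chi_squared(c(3, 2), c(0.5, 0.5), n_params = 3),
               "not enough classes")
})

test_that("demography fitting picks the generating model", {
  ctl <- ctl_test
  truth <- growth_model()
  p_true <- expected_sfs(truth, 18, 0, control = ctl)$p
  sim <- simulate_observed_sfs(p_true, 1e6, epsilon = 0.02, seed = 61)
  cands <- list(constant = demog_constant(),
                `growth r=1 t=13000` = demog_exponential(1, 13000),
                `growth r=1 t=7000` = demog_exponential(1, 7000),
                `growth r=2 t=13000` = demog_exponential(2, 13000))
  fd <- fit_demography(sim, cands, control = ctl)
  expect_equal(fd$label, "growth r=1 t=13000")
  expect_true(all(fd$loglik >= fd$candidate_table$loglik, na.rm = TRUE))
  expect_equal(fd$loglik, em_loglik(sim, fd$p, fd$epsilon), tolerance = 1e-9)

  # constant-model truth is recovered against growth alternatives
  p_c <- normalize_spectrum(equilibrium_sample_spectrum(0, 18))$p
  sim_c <- simulate_observed_sfs(p_c, 1e6, epsilon = 0, seed = 62)
  fd_c <- fit_demography(sim_c, cands, control = ctl)
  expect_equal(fd_c$label, "constant")
})
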