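make_sites <- function(scores, i = NULL, n = 18) {
  tibble::tibble(chrom = "chr1", pos = seq_along(scores),
                 i = i %||% rep(1L, length(scores)), n = n, score = scores)
}

test_that("integer binning rounds half away from zero and applies the cutoff", {
  sites <- make_sites(c(12.4, 12.5, 0.2, 40.4, 40.6, 41))
  binned <- bin_sites_by_score(sites, score_binning("integer"))
  got <- dplyr::filter(binned, .data$count > 0)
  expect_setequal(got$bin, c(12, 13, 0, 40))
  expect_equal(attr(binned, "n_excluded"), 2)  # 40.6 and 41 round above 40
  # conservation: every site is in exactly one bin or excluded
  expect_equal(sum(binned$count) + attr(binned, "n_excluded"), nrow(sites))
})

test_that("quarter binning uses 0.25-wide bins with a cutoff of 5", {
  sites <- make_sites(c(0.05, 0.13, 0.3, 4.99, 5.2))
  binned <- bin_sites_by_score(sites, score_binning("quarter"))
  got <- dplyr::filter(binned, .data$count > 0)
  expect_setequal(got$bin, c(0, 0.25, 5))
  expect_equal(attr(binned, "n_excluded"), 1)
})

test_that("binning validates its input", {
  sites <- make_sites(c(1, 2))
  sites$n <- c(18, 20)
  expect_error(bin_sites_by_score(sites), "same sample size")
  bad <- make_sites(1, i = 18L)
  expect_error(bin_sites_by_score(bad), "1..n-1")
  expect_error(bin_sites_by_score(make_sites(numeric(0))), "empty")
})

test_that("PHRED rescaling is rank-based, tie-sharing and monotone-invariant", {
  x <- c(3, 1, 4, 2)
  r <- phred_rescale(x)
  expect_equal(r[which.min(x)], 0)
  expect_equal(max(r), -log10(1 / 4))
  expect_equal(max(r), 0.602, tolerance = 1e-3)
  # invariance under strictly increasing transforms
  expect_equal(phred_rescale(exp(x)), r)
  # ties share outputs
  r2 <- phred_rescale(c(5, 5, 1, 0))
  expect_equal(r2[1], r2[2])
  expect_equal(r2[1], -log10(2 / 4))
})

test_that("the smoothing spline recovers a smooth monotone mapping", {
  # noiseless synthetic bin fits on a smooth curve
  bins <- 1:40
  log_s <- seq(-5.5, -2.5, length.out = 40)
  fits <- tibble::tibble(bin = c(0, bins), n_sites = 1000,
                         s_hat = c(0, -10^log_s), epsilon = 0.02,
                         loglik_point = 0, neutral = c(TRUE, rep(FALSE, 40)),
                         low_data = FALSE)
  attr(fits, "scheme") <- score_binning("integer")
  mp <- build_mapping(fits, df = 20)
  pred <- predict(mp, bins)
  expect_lt(max(abs(log10(-pred) - log_s)), 0.1)
  # neutral scores map to exactly 0
  expect_identical(predict(mp, 0.2), 0)
  # clamping beyond the fitted domain
  expect_equal(predict(mp, 41), predict(mp, 40))
  expect_equal(predict(mp, 100), predict(mp, 40))
})

test_that("build_mapping degrades df with a warning and rejects all-neutral", {
  fits <- tibble::tibble(bin = 0:8, s_hat = c(0, -10^seq(-5, -3, length.out = 8)),
                         neutral = c(TRUE, rep(FALSE, 8)))
  expect_warning(mp <- build_mapping(fits, df = 20), "df reduced")
  expect_s3_class(mp, "score_mapping")
  all_neutral <- tibble::tibble(bin = 0:3, s_hat = 0, neutral = TRUE)
  expect_error(build_mapping(all_neutral), "all bins are neutral")
})

test_that("bootstrap intervals are reproducible and collapse on degenerate bins", {
  cache <- growth_cache()
  p <- cache$P[cache_row(cache, -1e-4), ]
  sim <- simulate_observed_sfs(p, 2e4, epsilon = 0, seed = 71)
  sites <- tibble::tibble(chrom = "chr1", pos = 1, i = rep(sim$i, sim$count),
                          n = 18, score = 10)
  sites$pos <- seq_len(nrow(sites))
  binned <- bin_sites_by_score(sites)
  b1 <- bootstrap_mapping(binned, cache, B = 10, seed = 99)
  b2 <- bootstrap_mapping(binned, cache, B = 10, seed = 99)
  expect_identical(b1, b2)
  expect_true(b1$ci_lo <= b1$ci_hi)
  # a bin whose sites all share one derived count has zero bootstrap spread
  mono <- tibble::tibble(chrom = "chr1", pos = 1:50, i = 1L, n = 18, score = 5)
  bm <- bootstrap_mapping(bin_sites_by_score(mono), cache, B = 8, seed = 1)
  expect_equal(bm$boot_sd, 0)
})

test_that("label randomization preserves score and count multisets", {
  set.seed(2)
  sites <- make_sites(runif(200, 0, 10), i = sample(1:17, 200, replace = TRUE))
  perms <- randomize_labels(sites, R = 3, seed = 12)
  for (p in perms) {
    expect_equal(sort(p$score), sort(sites$score))
    expect_identical(p$i, sites$i)
  }
  expect_identical(randomize_labels(sites, R = 3, seed = 12), perms)
})

test_that("mapping tables round-trip through TSV", {
  fits <- tibble::tibble(bin = 0:3, n_sites = c(10, 20, 30, 40),
                         s_hat = c(0, -1e-5, -1e-4, -1e-3),
                         epsilon = 0.02, loglik_point = -c(1, 2, 3, 4),
                         neutral = c(TRUE, FALSE, FALSE, FALSE),
                         low_data = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping_table(fits, path)
  back <- read_mapping_table(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(fits))
})
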