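toy_mapping <- function() {
  fits <- tibble::tibble(bin = 0:20,
                         s_hat = c(0, -10^seq(-5, -3, length.out = 20)),
                         neutral = c(TRUE, rep(FALSE, 20)))
  attr(fits, "scheme") <- score_binning("integer")
  suppressWarnings(build_mapping(fits, df = 10))
}

test_that("site mapping is neutral-aware, deterministic and order-reversing", {
  mp <- toy_mapping()
  sites <- tibble::tibble(chrom = "chr1", pos = 1:6, i = 1L, n = 18,
                          score = c(0.1, 4, 4, 9, 13, 18))
  out <- map_sites_to_s(sites, mp)
  expect_equal(nrow(out), nrow(sites))
  expect_identical(out$s[1], 0)            # neutral bin passthrough
  expect_identical(out$s[2], out$s[3])     # equal scores, equal s
  # the mapping is decreasing in score, so site ranking reverses in s
  expect_true(all(diff(predict(mp, c(4, 9, 13, 18))) < 0))
})

test_that("the KDE integrates to one and resolves well-separated masses", {
  s <- c(rep(0, 500), rep(-1e-4, 500))
  d <- kde_dfe(s, bandwidth = 5e-6)
  expect_lt(abs(attr(d, "integral") - 1), 1e-3)
  # two modes, each within one bandwidth of its mass
  dens <- d$density
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  modes <- d$s[peaks[order(dens[peaks], decreasing = TRUE)][1:2]]
  expect_lt(min(abs(modes - 0)), 5e-6)
  expect_lt(min(abs(modes + 1e-4)), 5e-6)
  # invariant to input ordering
  d2 <- kde_dfe(sample(s), bandwidth = 5e-6)
  expect_equal(d2$density, d$density)
  expect_error(kde_dfe(numeric(0)), "at least one")
  expect_error(kde_dfe(0, bandwidth = -1), "bandwidth")
})

test_that("category summaries reproduce hand-computed proportions", {
  sites <- tibble::tibble(
    s = c(0, 0, -1e-4, -1e-4, rep(0, 8), rep(-5e-4, 4), rep(-2e-3, 4)),
    category = c(rep("a", 4), rep("b", 16)))
  out <- category_summary(sites, breaks = c(1e-4, 1e-3))
  a <- out[out$category == "a", ]
  expect_equal(a$n, 4)
  expect_equal(a$prop_neutral, 0.5)
  expect_equal(a$`prop_s_le_0.0001`, 0.5)
  expect_equal(a$log10_mean_s, log10(1e-4))
  b <- out[out$category == "b", ]
  expect_equal(b$prop_neutral, 0.5)
  expect_equal(b$`prop_s_le_0.001`, 0.25)
  expect_equal(b$`prop_s_gt_0.001`, 0.25)
  # proportions partition each category
  prop_cols <- grep("^prop", names(out), value = TRUE)
  expect_equal(rowSums(out[prop_cols]), c(1, 1), ignore_attr = TRUE)
  # all-neutral categories report missing log statistics
  allneut <- category_summary(tibble::tibble(s = c(0, 0), category = "x"))
  expect_true(is.na(allneut$log10_mean_s))
  # mean |s| over all sites in the worked 4-site example
  mix <- c(0, 0, -1e-4, -1e-4)
  expect_equal(log10(mean(abs(mix))), -4.30103, tolerance = 1e-5)
})

test_that("summaries are invariant to row order and chunking", {
  set.seed(8)
  sites <- tibble::tibble(s = -10^runif(200, -5, -3) * rbinom(200, 1, 0.7),
                          category = sample(c("x", "y"), 200, replace = TRUE))
  s1 <- category_summary(sites)
  s2 <- category_summary(sites[sample.int(200), ])
  expect_equal(s1, s2)
  chunks <- dplyr::bind_rows(sites[1:97, ], sites[98:200, ])
  expect_equal(category_summary(chunks), s1)
})

test_that("polarization bias is standardized and location-invariant", {
  sites <- tibble::tibble(
    score = c(1, 1, 2, 2), polarity = rep(c("ref_ancestral", "ref_derived"),
                                          each = 2), i = 3L)
  out <- polarization_bias(sites)
  expect_equal(out$standardized_diff, 1 / sd(c(1, 1, 2, 2)))
  expect_equal(out$prop_alt_ancestral, 0.5)
  # identical distributions give zero bias
  same <- tibble::tibble(score = rep(c(1, 2), 2),
                         polarity = rep(c("ref_ancestral", "ref_derived"),
                                        each = 2), i = 1L)
  expect_equal(polarization_bias(same)$standardized_diff, 0)
  # adding a constant to all scores changes nothing
  shifted <- dplyr::mutate(sites, score = score + 42)
  expect_equal(polarization_bias(shifted)$standardized_diff,
               out$standardized_diff)
  # a one-class bin is flagged, not computed
  oneclass <- tibble::tibble(score = c(1, 2), polarity = "ref_ancestral",
                             i = 2L)
  flagged <- polarization_bias(oneclass)
  expect_true(is.na(flagged$standardized_diff))
  expect_match(flagged$flag, "empty")
})

test_that("autoplot methods return ggplot objects", {
  mp <- toy_mapping()
  fits <- tibble::tibble(bin = 1:10, s_hat = -10^seq(-5, -3, length.out = 10),
                         neutral = FALSE)
  class(fits) <- c("mapping_table", class(fits))
  expect_s3_class(autoplot(fits, mapping = mp), "ggplot")
  d <- kde_dfe(c(0, 0, -1e-4), bandwidth = 5e-6)
  expect_s3_class(autoplot(d), "ggplot")
  expect_s3_class(plot_sfs(c(5, 3, 2), c(0.5, 0.3, 0.2)), "ggplot")
})
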