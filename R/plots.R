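#' Plot a score-to-s mapping table
#'
#' Per-bin maximum-likelihood coefficients on a log scale, optionally with
#' bootstrap interval ribbon and the fitted smoothing spline.
#'
#' @param object A [fit_score_bins()] mapping table.
#' @param ci Optional [bootstrap_mapping()] tibble to draw as a ribbon.
#' @param mapping Optional [build_mapping()] object to draw as a line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mapping_table <- function(object, ci = NULL, mapping = NULL, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !.data$neutral)
  dat$log10_s <- log10(-dat$s_hat)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$log10_s))
  if (!is.null(ci)) {
    rib <- dplyr::inner_join(dat, ci, by = "bin")
    rib <- dplyr::filter(rib, .data$ci_hi < 0)
    gg <- gg + ggplot2::geom_ribbon(
      data = rib,
      ggplot2::aes(ymin = log10(-.data$ci_lo), ymax = log10(-.data$ci_hi)),
      fill = "grey80")
  }
  gg <- gg + ggplot2::geom_point(colour = "red3")
  if (!is.null(mapping)) {
    line <- tidy(mapping)
    line <- dplyr::filter(line, .data$s < 0)
    gg <- gg + ggplot2::geom_line(
      data = line,
      ggplot2::aes(x = .data$score, y = log10(-.data$s)), colour = "blue3")
  }
  gg + ggplot2::labs(x = "score bin", y = "log10(-s)")
}

#' Plot a fitness-effect density
#'
#' @param object A [kde_dfe()] density table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dfe_density <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$s, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "selection coefficient s", y = "density")
}

#' Plot an observed SFS against a fitted spectrum
#'
#' @param counts Observed SFS (tibble with `i`, `count`).
#' @param fitted Optional fitted class probabilities (vector or tibble with
#'   `p`), drawn as expected counts at the observed total.
#' @return A ggplot object.
#' @export
plot_sfs <- function(counts, fitted = NULL) {
  cv <- counts_vec(counts)
  dat <- tibble::tibble(i = seq_along(cv), count = cv)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$i, y = .data$count)) +
    ggplot2::geom_col(fill = "grey60")
  if (!is.null(fitted)) {
    pv <- if (is.data.frame(fitted)) fitted$p else fitted
    dat2 <- tibble::tibble(i = seq_along(pv), expected = pv * sum(cv))
    gg <- gg + ggplot2::geom_point(
      data = dat2, ggplot2::aes(y = .data$expected), colour = "red3")
  }
  gg + ggplot2::labs(x = "derived-allele count i", y = "sites")
}
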