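#' Map scored sites to selection coefficients
#'
#' @param sites A site table with a `score` column.
#' @param mapping A [build_mapping()] result.
#' @return The site table with an added `s` column (0 for neutral-bin scores),
#'   aligned 1:1 with the input rows.
#' @export
map_sites_to_s <- function(sites, mapping) {
  stopifnot(inherits(mapping, "score_mapping"))
  dplyr::mutate(tibble::as_tibble(sites), s = predict(mapping, .data$score))
}

#' Kernel density estimate of a fitness-effect distribution
#'
#' Gaussian-kernel density of mapped selection coefficients, with the
#' bandwidth given directly as the kernel standard deviation on the `s` scale
#' (default 5e-6; 2.5e-6 and 1e-6 are useful for finer structure).
#'
#' @param s Selection coefficients (one per site).
#' @param bandwidth Kernel SD on the `s` scale (default `5e-6`).
#' @param n_grid Number of evaluation points (default 2048).
#' @param from,to Evaluation range; defaults extend 6 bandwidths beyond the
#'   data range so the density integrates to 1.
#' @return A tibble of class `dfe_density` with columns `s`, `density` and
#'   attributes `bandwidth` and `integral` (trapezoid integral over the
#'   grid).
#' @export
kde_dfe <- function(s, bandwidth = 5e-6, n_grid = 2048,
                    from = NULL, to = NULL) {
  if (length(s) < 1) abort("at least one value is required")
  if (!is.numeric(bandwidth) || bandwidth <= 0) abort("bandwidth must be > 0")
  from <- from %||% (min(s) - 6 * bandwidth)
  to <- to %||% (max(s) + 6 * bandwidth)
  d <- density(s, bw = bandwidth, kernel = "gaussian", n = n_grid,
               from = from, to = to)
  out <- tibble::tibble(s = d$x, density = d$y)
  dx <- diff(out$s)
  integral <- sum((out$density[-1] + out$density[-nrow(out)]) / 2 * dx)
  attr(out, "bandwidth") <- bandwidth
  attr(out, "integral") <- integral
  class(out) <- c("dfe_density", class(out))
  out
}

#' Summarize fitness effects per functional category
#'
#' For each category: the number of sites, the proportion of sites in each
#' range of a partition of the `s` axis (the neutral mass `s = 0` plus
#' magnitude intervals defined by `breaks`), and the base-10 logarithms of the
#' mean and standard deviation of `|s|` over the selected (`s < 0`) sites.
#' Categories with no selected sites report the log statistics as `NA`.
#'
#' @param sites A tibble with columns `s` and `category` (rows with `NA`
#'   category are grouped under `"other"`).
#' @param breaks Increasing magnitude cut points partitioning the selected
#'   range (default `c(1e-4, 1e-3)`, giving ranges `(0, 1e-4]`,
#'   `(1e-4, 1e-3]` and `> 1e-3`).
#' @return A tibble with one row per category: `category`, `n`,
#'   `prop_neutral`, one `prop_*` column per magnitude range,
#'   `log10_mean_s`, `log10_sd_s`.  Proportions sum to 1 per category.
#' @export
category_summary <- function(sites, breaks = c(1e-4, 1e-3)) {
  if (!all(c("s", "category") %in% names(sites))) {
    abort("sites must have columns 's' and 'category'")
  }
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0)) {
    abort("breaks must be strictly increasing and positive")
  }
  edges <- c(0, breaks, Inf)
  labs <- character(length(edges) - 1)
  for (k in seq_along(labs)) {
    labs[k] <- if (is.finite(edges[k + 1])) {
      sprintf("prop_s_le_%g", edges[k + 1])
    } else {
      sprintf("prop_s_gt_%g", edges[k])
    }
  }
  tbl <- dplyr::mutate(tibble::as_tibble(sites),
                       category = dplyr::coalesce(as.character(.data$category),
                                                  "other"))
  dplyr::group_by(tbl, .data$category) |>
    dplyr::group_modify(function(g, key) {
      m <- abs(g$s)
      sel <- g$s < 0
      props <- vapply(seq_along(labs), function(k) {
        mean(sel & m > edges[k] & m <= edges[k + 1])
      }, numeric(1))
      out <- tibble::tibble(n = nrow(g), prop_neutral = mean(!sel))
      for (k in seq_along(labs)) out[[labs[k]]] <- props[k]
      out$log10_mean_s <- if (any(sel)) log10(mean(m[sel])) else NA_real_
      out$log10_sd_s <- if (sum(sel) >= 2) log10(sd(m[sel])) else NA_real_
      out
    }) |>
    dplyr::ungroup()
}

#' Reference/alternative polarization bias of a score
#'
#' For each derived-allele-count bin, computes the absolute difference
#' between the mean score at sites where the reference allele is ancestral
#' and at sites where it is derived, divided by the standard deviation of the
#' scores over both kinds of sites combined.  Also reports the proportion of
#' sites where the alternative allele is ancestral (i.e. reference = derived)
#' per bin.  A score free of reference bias gives values near 0.
#'
#' @param sites A tibble with columns `score`, `polarity` (values
#'   `"ref_ancestral"` / `"ref_derived"`) and `i` (derived count).
#' @return A tibble with one row per derived count: `i`, `n`,
#'   `standardized_diff` (`NA` when a polarity class is empty or the pooled
#'   SD is 0, with `flag` saying why), `prop_alt_ancestral`.
#' @export
polarization_bias <- function(sites) {
  req <- c("score", "polarity", "i")
  if (!all(req %in% names(sites))) {
    abort(paste0("sites must have columns: ", paste(req, collapse = ", ")))
  }
  bad <- setdiff(unique(sites$polarity), c("ref_ancestral", "ref_derived"))
  if (length(bad) > 0) {
    abort("polarity must be 'ref_ancestral' or 'ref_derived'")
  }
  dplyr::group_by(tibble::as_tibble(sites), .data$i) |>
    dplyr::group_modify(function(g, key) {
      anc <- g$score[g$polarity == "ref_ancestral"]
      der <- g$score[g$polarity == "ref_derived"]
      pooled_sd <- sd(g$score)
      flag <- if (length(anc) == 0 || length(der) == 0) {
        "one polarity class empty"
      } else if (!is.finite(pooled_sd) || pooled_sd == 0) {
        "pooled SD is zero"
      } else {
        NA_character_
      }
      tibble::tibble(
        n = nrow(g),
        standardized_diff = if (is.na(flag)) {
          abs(mean(anc) - mean(der)) / pooled_sd
        } else {
          NA_real_
        },
        prop_alt_ancestral = mean(g$polarity == "ref_derived"),
        flag = flag)
    }) |>
    dplyr::ungroup()
}

#' Write a category summary or density table to TSV
#'
#' @param tab A tibble (e.g. from [category_summary()] or [kde_dfe()]).
#' @param path File path.
#' @export
write_summary_tsv <- function(tab, path) {
  readr::write_tsv(tibble::as_tibble(tab), path)
  invisible(path)
}
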