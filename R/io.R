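#' Read and write site tables
#'
#' The native dialect is a flat TSV with columns `chrom`, `pos` (1-based),
#' `i` (derived-allele count), `n` (haploid sample size), `score`, and
#' optional `category`, `stratum` and `polarity` columns (missing values as
#' `NA`).  Reading validates every record: derived counts must be polymorphic
#' (`1 <= i <= n - 1`) and scores finite; rejected records are collected into
#' a report attached as the `rejected` attribute (with a reason per record),
#' and accepted/rejected totals are reported via a message.
#'
#' @param path File path.
#' @return `read_site_table()` returns a tibble of validated records with a
#'   `rejected` attribute; `write_site_table()` returns `path` invisibly.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  req <- c("chrom", "pos", "i", "n", "score")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) {
    abort(paste0("site table is missing required columns: ",
                 paste(miss, collapse = ", ")))
  }
  for (opt in c("category", "stratum", "polarity")) {
    if (!opt %in% names(tab)) tab[[opt]] <- NA_character_
    tab[[opt]] <- as.character(tab[[opt]])
  }
  reason <- rep(NA_character_, nrow(tab))
  reason[!is.finite(tab$score)] <- "non-finite score"
  reason[is.na(tab$i) | is.na(tab$n)] <- "missing i or n"
  fixed <- !is.na(tab$i) & !is.na(tab$n) & (tab$i < 1 | tab$i > tab$n - 1)
  reason[fixed] <- "monomorphic"
  ok <- is.na(reason)
  rejected <- tibble::tibble(row = which(!ok), reason = reason[!ok])
  out <- tab[ok, c(req, "category", "stratum", "polarity")]
  message(sprintf("read_site_table: %d accepted, %d rejected", sum(ok),
                  sum(!ok)))
  attr(out, "rejected") <- rejected
  out
}

#' @rdname read_site_table
#' @param sites A site table tibble.
#' @export
write_site_table <- function(sites, path) {
  cols <- intersect(c("chrom", "pos", "i", "n", "score", "category",
                      "stratum", "polarity"), names(sites))
  readr::write_tsv(sites[cols], path)
  invisible(path)
}

#' Read and write observed-SFS TSV files
#'
#' Columns `i` and `count`, preceded by a `# n <value>` header comment.
#'
#' @param path File path.
#' @return `read_observed_sfs()` returns a tibble with attribute `n`.
#' @export
read_observed_sfs <- function(path) {
  hdr <- readLines(path, n = 5)
  nline <- grep("^# n\t", hdr, value = TRUE)
  if (length(nline) == 0) abort("observed-SFS file lacks a '# n' header")
  n <- as.integer(strsplit(nline[1], "\t")[[1]][2])
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("i", "count") %in% names(tab))) {
    abort("observed-SFS file must have columns i and count")
  }
  if (nrow(tab) != n - 1) abort("SFS length does not match the header n")
  attr(tab, "n") <- n
  tab
}

#' @rdname read_observed_sfs
#' @param sfs A tibble with columns `i`, `count` and attribute `n` (or `n`
#'   given explicitly).
#' @param n Haploid sample size.
#' @export
write_observed_sfs <- function(sfs, path, n = attr(sfs, "n")) {
  if (is.null(n)) abort("n is required (attribute or argument)")
  writeLines(sprintf("# n\t%d", as.integer(n)), path)
  readr::write_tsv(sfs[c("i", "count")], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Write an expected-SFS TSV (columns i, e, p with metadata header)
#'
#' @param sfs A tibble with columns `i`, `e` (and optionally `p`).
#' @param path File path.
#' @param n Haploid sample size.
#' @param S Scaled selection coefficient for the header.
#' @param model_label Demography label for the header.
#' @export
write_expected_sfs <- function(sfs, path, n = attr(sfs, "n"), S = NA,
                               model_label = "unknown") {
  if (!"p" %in% names(sfs)) sfs$p <- sfs$e / sum(sfs$e)
  writeLines(c(sprintf("# n\t%d", as.integer(n)),
               sprintf("# S\t%g", S),
               sprintf("# model\t%s", model_label)), path)
  readr::write_tsv(sfs[c("i", "e", "p")], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read scored sites from a VCF plus a score annotation table
#'
#' A thin adaptor for biallelic SNPs: derived-allele counts are taken as the
#' number of alternative alleles across genotypes (the alternative allele is
#' assumed derived unless a `polarity` column in the annotation says
#' otherwise) and `n` is twice the number of samples with calls, which must
#' be constant across retained sites.  Scores are joined from a TSV with
#' columns `chrom`, `pos`, `score` (optionally `category`, `stratum`,
#' `polarity`).  Monomorphic and multiallelic records are dropped with a
#' count reported.  Requires the `vcfR` package.
#'
#' @param vcf_path Path to a VCF file.
#' @param scores_path Path to the annotation TSV.
#' @return A site table tibble.
#' @export
read_vcf_sites <- function(vcf_path, scores_path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("the vcfR package is required for VCF input")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  alt_count <- function(g) {
    alleles <- unlist(strsplit(g[!is.na(g)], "[/|]"))
    c(sum(alleles == "1"), length(alleles))
  }
  counts <- t(apply(gt, 1, alt_count))
  n_chroms <- counts[, 2]
  n <- max(n_chroms)
  ok <- biallelic & n_chroms == n & counts[, 1] >= 1 & counts[, 1] <= n - 1
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(sprintf(
      "read_vcf_sites: dropped %d record(s) (multiallelic, monomorphic or incomplete)",
      dropped))
  }
  sites <- tibble::tibble(chrom = fix[ok, "CHROM"],
                          pos = as.integer(fix[ok, "POS"]),
                          i = as.integer(counts[ok, 1]), n = as.integer(n))
  ann <- readr::read_tsv(scores_path, show_col_types = FALSE)
  if (!all(c("chrom", "pos", "score") %in% names(ann))) {
    abort("score annotation must have columns chrom, pos, score")
  }
  out <- dplyr::inner_join(sites, ann, by = c("chrom", "pos"))
  for (opt in c("category", "stratum", "polarity")) {
    if (!opt %in% names(out)) out[[opt]] <- NA_character_
  }
  out
}

#' Filter a site table with a BED mask
#'
#' BED intervals are 0-based half-open and are converted to the 1-based
#' coordinates of the site table.  Overlapping intervals are merged per
#' chromosome before lookup.
#'
#' @param sites A site table.
#' @param bed_path Path to a BED file (columns chrom, start, end; no header).
#' @param keep If `TRUE` (default) keep sites inside the mask, else keep
#'   sites outside it.
#' @return The filtered site table.
#' @export
apply_bed_mask <- function(sites, bed_path, keep = TRUE) {
  bed <- readr::read_tsv(bed_path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", comment = "#")
  inside <- rep(FALSE, nrow(sites))
  for (ch in unique(bed$chrom)) {
    iv <- bed[bed$chrom == ch, ]
    iv <- iv[order(iv$start), ]
    # merge overlapping/adjacent intervals
    merged_s <- integer(0); merged_e <- integer(0)
    for (k in seq_len(nrow(iv))) {
      if (length(merged_e) > 0 && iv$start[k] <= merged_e[length(merged_e)]) {
        merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], iv$end[k])
      } else {
        merged_s <- c(merged_s, iv$start[k])
        merged_e <- c(merged_e, iv$end[k])
      }
    }
    rows <- which(sites$chrom == ch)
    if (length(rows) == 0) next
    pos0 <- sites$pos[rows] - 1L  # 0-based position of the base
    idx <- findInterval(pos0, merged_s)
    hit <- idx > 0 & pos0 < merged_e[pmax(idx, 1)]
    inside[rows] <- hit
  }
  sites[if (keep) inside else !inside, ]
}

#' CpG dinucleotide density of a sequence window
#'
#' The proportion of CpG dinucleotides over the `length - 1` dinucleotide
#' positions of a window (canonically 151 bases: +/- 75 bp around a site;
#' shorter windows at contig edges are allowed).  The conventional filter
#' keeps sites with density strictly below 0.05.
#'
#' @param window DNA sequence string(s) over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return Numeric density in `[0, 1]` per input string.
#' @export
cpg_density <- function(window) {
  vapply(window, function(s) {
    if (!nzchar(s)) abort("empty sequence")
    s <- toupper(s)
    if (grepl("[^ACGTN]", s)) abort("sequence must be over A, C, G, T, N")
    L <- nchar(s)
    if (L < 2) return(0)
    hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
    n_cg <- if (hits[1] == -1) 0L else length(hits)
    n_cg / (L - 1)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Filter sites by CpG density
#'
#' @param sites A site table with a `cpg_density` column (computed upstream
#'   from the reference sequence).
#' @param threshold Keep sites with density strictly below this value
#'   (default 0.05).
#' @return The filtered site table.
#' @export
filter_low_cpg <- function(sites, threshold = 0.05) {
  if (!"cpg_density" %in% names(sites)) {
    abort("sites must have a 'cpg_density' column")
  }
  sites[sites$cpg_density < threshold, ]
}
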