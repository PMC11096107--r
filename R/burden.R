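#' Configuration for the windowed rare-variant density scan
#'
#' Defaults mirror the published screen: 500-bp windows over the linkage
#' region, rarity defined as panel allele frequency < 0.002, family-wise error
#' rate 0.05 under Bonferroni, one-sided test for enrichment in cases.
#'
#' @param region A [genomic_interval] to scan (default the 3.2-Mb chr15 linkage
#'   region, chr15:86,206,001-89,412,500).
#' @param bin_width Window size in bases (default 500).
#' @param rare_threshold Allele-frequency cutoff; a variant is rare iff its
#'   panel AF is strictly below this (default 0.002).
#' @param alpha Family-wise error rate for the Bonferroni threshold
#'   (default 0.05).
#' @param side Test direction; only `"cases"` (enrichment in cases) is
#'   meaningful for this screen.
#' @param unit Counting unit for the 2x2 tables: `"carriers"` (individuals
#'   with >= 1 rare variant in the window; default) or `"alleles"` (summed
#'   alternate-allele counts). The publication does not pin the construction;
#'   both are exposed.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(region = genomic_interval("chr15", 86206001, 89412500),
                        bin_width = 500, rare_threshold = 0.002, alpha = 0.05,
                        side = "cases", unit = c("carriers", "alleles")) {
  stopifnot(inherits(region, "genomic_interval"))
  if (!is_count(bin_width) || bin_width < 1) stop_input("`bin_width` must be >= 1")
  if (!(rare_threshold > 0 && rare_threshold < 1)) stop_input("`rare_threshold` must be in (0,1)")
  if (!(alpha > 0 && alpha < 1)) stop_input("`alpha` must be in (0,1)")
  structure(list(region = region, bin_width = bin_width,
                 rare_threshold = rare_threshold, alpha = alpha,
                 side = side, unit = match.arg(unit)),
            class = "scan_config")
}

#' Partition a region into fixed-width bins
#'
#' Consecutive, non-overlapping, left-aligned windows starting at
#' `region$start`; the last bin is truncated at `region$end` when the region
#' length is not divisible by `bin_width`. The union of bins equals the region
#' exactly.
#'
#' @param region A [genomic_interval].
#' @param bin_width Window size in bases.
#' @return List of [genomic_interval] bins.
#' @examples
#' length(make_bins(genomic_interval("chr15", 86206001, 89412500), 500)) # 6413
#' @export
make_bins <- function(region, bin_width) {
  stopifnot(inherits(region, "genomic_interval"))
  if (!is_count(bin_width) || bin_width < 1) stop_input("`bin_width` must be >= 1")
  starts <- seq(region$start, region$end, by = bin_width)
  lapply(starts, function(s) {
    genomic_interval(region$chrom, s, min(s + bin_width - 1, region$end))
  })
}

# 1-based bin index of positions within region; NA outside
bin_index <- function(region, bin_width, chrom, pos) {
  idx <- (pos - region$start) %/% bin_width + 1
  idx[!(chrom == region$chrom & pos >= region$start & pos <= region$end)] <- NA
  idx
}

#' Classify cohort variants as rare against a frequency panel
#'
#' A variant is rare iff its panel allele frequency is strictly below
#' `rare_threshold`. Variants absent from the panel are treated as AF 0 and
#' hence rare. Keys are matched on the normalized `chrom:pos:ref:alt` form, so
#' cohort variants must be normalized consistently with the panel (see
#' [normalize_variant()]).
#'
#' @param cohort A [cohort_variants].
#' @param panel A [panel_frequencies].
#' @param rare_threshold AF cutoff (default 0.002).
#' @return Character vector of rare variant keys.
#' @export
classify_rare <- function(cohort, panel, rare_threshold = 0.002) {
  stopifnot(inherits(cohort, "cohort_variants"))
  keys <- vkeys(cohort$variants)
  af <- unname(panel[keys])
  af[is.na(af)] <- 0
  keys[af < rare_threshold]
}

#' Per-bin 2x2 case/control tables of rare-variant carriers
#'
#' For each window, counts per group either the individuals carrying at least
#' one non-missing alternate allele at any rare variant in the window
#' (`unit = "carriers"`), or the summed alternate-allele counts
#' (`unit = "alleles"`). Missing genotypes never contribute carriers and never
#' shrink denominators. Variants outside the region are ignored and their
#' number reported.
#'
#' @param cohort A [cohort_variants].
#' @param rare_set Keys returned by [classify_rare()].
#' @param config A [scan_config].
#' @return A data.frame with one row per bin: `bin_start`, `bin_end`, `a`
#'   (case carriers), `b`, `c` (control carriers), `d`; attribute
#'   `n_outside_region` counts the skipped variants.
#' @export
count_bin_carriers <- function(cohort, rare_set, config) {
  stopifnot(inherits(cohort, "cohort_variants"), inherits(config, "scan_config"))
  region <- config$region; bw <- config$bin_width
  bins <- make_bins(region, bw)
  m <- length(bins)
  keys <- vkeys(cohort$variants)
  rare <- keys %in% rare_set
  idx <- bin_index(region, bw, cohort$variants$chrom, cohort$variants$pos)
  use <- rare & !is.na(idx)
  n_outside <- sum(rare & is.na(idx))
  is_case <- cohort$group == "case"
  n_cases <- sum(is_case); n_controls <- sum(!is_case)
  a <- integer(m); cc <- integer(m)
  if (any(use)) {
    g <- cohort$genotypes[use, , drop = FALSE]
    for (b in unique(idx[use])) {
      gb <- g[idx[use] == b, , drop = FALSE]
      if (config$unit == "carriers") {
        carrier <- colSums(!is.na(gb) & gb > 0) > 0
        a[b] <- sum(carrier & is_case)
        cc[b] <- sum(carrier & !is_case)
      } else {
        alleles <- colSums(gb, na.rm = TRUE)
        a[b] <- sum(alleles[is_case])
        cc[b] <- sum(alleles[!is_case])
      }
    }
  }
  if (config$unit == "carriers") {
    b_col <- n_cases - a; d_col <- n_controls - cc
  } else {
    # allele counting: denominators are 2n chromosomes
    b_col <- 2L * n_cases - a; d_col <- 2L * n_controls - cc
  }
  out <- data.frame(
    bin_start = vapply(bins, function(x) x$start, numeric(1)),
    bin_end = vapply(bins, function(x) x$end, numeric(1)),
    a = a, b = b_col, c = cc, d = d_col
  )
  attr(out, "n_outside_region") <- n_outside
  out
}

#' Run the windowed rare-variant density scan
#'
#' Rarity classification, per-bin 2x2 tables, one-sided Fisher p-values
#' ([fisher_exact_one_sided()]) and the Bonferroni verdict at
#' `alpha / n_bins`. Bins are ranked by ascending p, ties broken by genomic
#' position.
#'
#' @param cohort A [cohort_variants] with both cases and controls.
#' @param panel A [panel_frequencies].
#' @param config A [scan_config].
#' @return An object of class `scan_result`: data.frame `bins` (bin coords,
#'   a, b, c, d, p, neg_log10_p, significant, rank), plus `threshold`,
#'   `n_bins`, `config`.
#' @export
run_scan <- function(cohort, panel, config = scan_config()) {
  stopifnot(inherits(cohort, "cohort_variants"))
  is_case <- cohort$group == "case"
  if (sum(is_case) == 0L || sum(!is_case) == 0L) {
    stop_input("scan requires at least one case and one control sample")
  }
  rare <- classify_rare(cohort, panel, config$rare_threshold)
  tab <- count_bin_carriers(cohort, rare, config)
  m <- nrow(tab)
  p <- numeric(m); l10 <- numeric(m)
  for (i in seq_len(m)) {
    if (tab$a[i] == 0L) { p[i] <- 1; l10[i] <- 0; next }  # upper tail from 0 is 1
    ft <- fisher_exact_one_sided(tab$a[i], tab$b[i], tab$c[i], tab$d[i])
    p[i] <- ft$p; l10[i] <- ft$log10_p
  }
  threshold <- config$alpha / m
  tab$p <- p
  tab$neg_log10_p <- -l10
  tab$significant <- p < threshold
  tab$rank <- rank_with_position_ties(p, tab$bin_start)
  structure(list(bins = tab, threshold = threshold, n_bins = m,
                 n_rare = length(rare),
                 n_outside_region = attr(tab, "n_outside_region"),
                 config = config),
            class = "scan_result")
}

# rank by ascending p, ties broken by genomic position
rank_with_position_ties <- function(p, pos) {
  o <- order(p, pos)
  r <- integer(length(p)); r[o] <- seq_along(p)
  r
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d bins of %d bp over %s\n", x$n_bins,
              x$config$bin_width, format_interval(x$config$region)))
  cat(sprintf("  rare variants used: %d; Bonferroni threshold: %.3g\n",
              x$n_rare, x$threshold))
  sig <- x$bins[x$bins$significant, , drop = FALSE]
  cat(sprintf("  significant bins: %d\n", nrow(sig)))
  if (nrow(sig) > 0) {
    top <- sig[order(sig$p), , drop = FALSE][seq_len(min(5, nrow(sig))), ]
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s:%d-%d  a=%d c=%d  p=%.3g\n", x$config$region$chrom,
                  top$bin_start[i], top$bin_end[i], top$a[i], top$c[i], top$p[i]))
    }
  }
  invisible(x)
}

#' Write a scan result as TSV
#' @param x A `scan_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(x, path) {
  stopifnot(inherits(x, "scan_result"))
  hdr <- c(sprintf("# rare-variant density scan over %s", format_interval(x$config$region)),
           sprintf("# bin_width=%d bp; rare AF < %g; Bonferroni threshold = %.6g (alpha=%g / m=%d)",
                   x$config$bin_width, x$config$rare_threshold, x$threshold,
                   x$config$alpha, x$n_bins),
           "# coordinates 1-based inclusive; a/c = case/control carriers; p one-sided Fisher")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x$bins, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
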