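#' Coverage track over fixed-width bins
#'
#' Mean read depth per fixed-width bin over a declared interval, emulating a
#' per-cell-type single-nucleus ATAC coverage track. Bins are anchored at the
#' declared interval's start (offset 0), so a query region always sees the same
#' precomputed bins.
#'
#' @param cell_type Cell-type name.
#' @param interval A [genomic_interval] the bins tile.
#' @param bin_width Bin width in bases (default 100).
#' @param depths Numeric vector of per-bin mean depths (>= 0), of length
#'   `ceiling(interval_length(interval) / bin_width)`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(cell_type, interval, bin_width = 100, depths) {
  stopifnot(inherits(interval, "genomic_interval"))
  if (!is_count(bin_width) || bin_width < 1) stop_input("`bin_width` must be a positive integer")
  nb <- ceiling(interval_length(interval) / bin_width)
  depths <- as.numeric(depths)
  if (length(depths) != nb) {
    stop_input("depths length %d != number of bins %d", length(depths), nb)
  }
  if (anyNA(depths) || any(depths < 0)) stop_input("depths must be >= 0")
  structure(list(cell_type = as.character(cell_type), interval = interval,
                 bin_width = bin_width, depths = depths),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s over %s, %d-bp bins (%d bins)\n",
              x$cell_type, format_interval(x$interval), x$bin_width,
              length(x$depths)))
  invisible(x)
}

#' Read a bedGraph file onto fixed-width bins
#'
#' bedGraph records are 0-based half-open; they are converted to the package's
#' 1-based inclusive coordinates and resampled onto fixed bins anchored at the
#' declared interval start. Each bin's depth is the coverage-weighted mean of
#' the records overlapping it; bins with no coverage get 0.
#'
#' @param path bedGraph file path (4 columns: chrom, start, end, value).
#' @param bin_width Bin width in bases (default 100).
#' @param interval Optional [genomic_interval] the track is declared over;
#'   inferred as `chrom:1-max(end)` from the data when `NULL`. Required for an
#'   empty file.
#' @param cell_type Track name; defaults to the file name without extension.
#' @return A [coverage_track].
#' @export
read_bedgraph <- function(path, bin_width = 100, interval = NULL, cell_type = NULL) {
  if (is.null(cell_type)) cell_type <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    if (is.null(interval)) {
      stop_input("empty bedGraph '%s': supply `interval` to build a zero track", path)
    }
    nb <- ceiling(interval_length(interval) / bin_width)
    return(coverage_track(cell_type, interval, bin_width, rep(0, nb)))
  }
  f <- strsplit(lines, "[ \t]+")
  if (any(lengths(f) < 4L)) stop_input("bedGraph '%s': need 4 columns", path)
  chrom <- vapply(f, `[`, "", 1L)
  s0 <- as.numeric(vapply(f, `[`, "", 2L))
  e0 <- as.numeric(vapply(f, `[`, "", 3L))
  val <- as.numeric(vapply(f, `[`, "", 4L))
  if (anyNA(s0) || anyNA(e0) || anyNA(val)) stop_input("bedGraph '%s': non-numeric fields", path)
  if (any(val < 0)) stop_input("bedGraph '%s': negative value", path)
  if (length(unique(chrom)) > 1L) stop_input("bedGraph '%s': multiple chromosomes", path)
  if (any(e0 <= s0)) stop_input("bedGraph '%s': empty or inverted interval", path)
  o <- order(s0)
  if (any(s0[o][-1] < e0[o][-length(o)])) {
    stop_input("bedGraph '%s': overlapping input intervals", path)
  }
  # 0-based half-open (s0, e0) covers the same bases as 1-based s0+1 .. e0
  s1 <- s0 + 1; e1 <- e0
  if (is.null(interval)) interval <- genomic_interval(chrom[1], 1, max(e1))
  nb <- ceiling(interval_length(interval) / bin_width)
  num <- numeric(nb); den <- numeric(nb)
  for (i in seq_along(s1)) {
    lo <- max(s1[i], interval$start); hi <- min(e1[i], interval$end)
    if (lo > hi) next
    b1 <- (lo - interval$start) %/% bin_width + 1
    b2 <- (hi - interval$start) %/% bin_width + 1
    for (b in b1:b2) {
      bin_lo <- interval$start + (b - 1) * bin_width
      bin_hi <- min(bin_lo + bin_width - 1, interval$end)
      ov <- min(hi, bin_hi) - max(lo, bin_lo) + 1
      num[b] <- num[b] + ov * val[i]
      den[b] <- den[b] + ov
    }
  }
  coverage_track(cell_type, interval, bin_width, ifelse(den > 0, num / den, 0))
}

#' Write a coverage track as bedGraph
#'
#' One 0-based half-open record per bin. Reading the file back with the same
#' `bin_width` and declared interval reproduces the track exactly.
#'
#' @param track A [coverage_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  iv <- track$interval
  nb <- length(track$depths)
  s1 <- iv$start + (seq_len(nb) - 1) * track$bin_width
  e1 <- pmin(s1 + track$bin_width - 1, iv$end)
  writeLines(sprintf("%s\t%d\t%d\t%s", iv$chrom, s1 - 1, e1,
                     format(track$depths, scientific = FALSE, trim = TRUE, digits = 15)),
             path)
  invisible(path)
}
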