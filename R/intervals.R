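#' Genomic interval (1-based, inclusive)
#'
#' The universal coordinate carrier of the package. All internal coordinates
#' are 1-based and inclusive, matching the convention of printed GRCh38
#' positions; conversion to 0-based half-open happens only at format
#' boundaries (bedGraph/BED).
#'
#' @param chrom Chromosome name, e.g. `"chr15"`.
#' @param start,end 1-based inclusive positions; `start >= 1`, `end >= start`.
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("chr15", 86206001, 89412500)
#' interval_length(gi)  # 3,206,500 bases
#' @export
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) || !nzchar(chrom)) {
    stop_input("`chrom` must be a non-empty string")
  }
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || start < 1 || start != floor(start)) {
    stop_input("`start` must be an integer >= 1 (got %s)", format(start))
  }
  if (is.na(end) || end < start || end != floor(end)) {
    stop_input("`end` must be an integer >= start (got start=%s, end=%s)",
               format(start), format(end))
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s (%s bp)\n", format_interval(x),
              format(interval_length(x), big.mark = ",")))
  invisible(x)
}

#' Length of a 1-based inclusive interval
#' @param x A `genomic_interval`.
#' @return `end - start + 1`.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start + 1
}

#' Parse a region string like "chr15:86206001-89412500"
#' @param s Region string `chrom:start-end` (commas in numbers allowed).
#' @return A `genomic_interval`.
#' @export
parse_region <- function(s) {
  s <- gsub(",", "", s, fixed = TRUE)
  m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4L) stop_input("cannot parse region string '%s'", s)
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}

format_interval <- function(x) sprintf("%s:%d-%d", x$chrom, x$start, x$end)

# TRUE when position (chrom,pos) falls inside interval
interval_contains <- function(x, chrom, pos) {
  chrom == x$chrom & pos >= x$start & pos <= x$end
}

intervals_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start <= b$end && b$start <= a$end
}
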