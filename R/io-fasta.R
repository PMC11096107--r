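#' Anchored reference sequence
#'
#' A plus-strand DNA sequence anchored at a genomic position, so that local
#' string offsets map to the 1-based coordinates printed for the locus.
#'
#' @param chrom Chromosome name.
#' @param start 1-based genomic position of the first base of `seq`.
#' @param seq DNA string over A/C/G/T/N.
#' @return An object of class `ref_seq`.
#' @export
ref_seq <- function(chrom, start, seq) {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", seq)) stop_input("sequence must be over {A,C,G,T,N}")
  if (!is_count(start) || start < 1) stop_input("`start` must be a positive integer")
  structure(list(chrom = chrom, start = as.numeric(start), seq = seq),
            class = "ref_seq")
}

#' @export
print.ref_seq <- function(x, ...) {
  cat(sprintf("<ref_seq> %s:%d-%d (%d bp)\n", x$chrom, x$start,
              x$start + nchar(x$seq) - 1, nchar(x$seq)))
  invisible(x)
}

# genomic position -> string offset (1-based), with bounds check
ref_offset <- function(ref, pos) {
  off <- pos - ref$start + 1
  if (any(off < 1 | off > nchar(ref$seq))) {
    stop_input("position %s outside reference %s:%d-%d",
               paste(pos[off < 1 | off > nchar(ref$seq)], collapse = ","),
               ref$chrom, ref$start, ref$start + nchar(ref$seq) - 1)
  }
  off
}

#' Reference bases at a genomic position
#' @param ref A [ref_seq].
#' @param pos 1-based genomic position of the first base.
#' @param len Number of bases (default 1).
#' @return The substring of the reference at `pos`.
#' @export
ref_base_at <- function(ref, pos, len = 1L) {
  off <- ref_offset(ref, pos)
  substr(ref$seq, off, off + len - 1L)
}

#' Read / write an anchored reference as FASTA
#'
#' The FASTA header encodes the anchor as `chrom:start-end`; a bare header is
#' read with `start = 1`. Single-record files only.
#'
#' @param path FASTA path.
#' @return `read_fasta_ref` returns a [ref_seq]; `write_fasta_ref` returns
#'   `path` invisibly.
#' @export
read_fasta_ref <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^>", lines)
  if (length(hdr_i) != 1L || hdr_i != 1L) {
    stop_input("FASTA '%s' must contain exactly one record", path)
  }
  name <- sub("^>\\s*", "", lines[1])
  name <- strsplit(name, "\\s+")[[1]][1]
  seq <- paste(lines[-1], collapse = "")
  m <- regmatches(name, regexec("^([^:]+):([0-9]+)-([0-9]+)$", name))[[1]]
  if (length(m) == 4L) {
    ref_seq(m[2], as.numeric(m[3]), seq)
  } else {
    ref_seq(name, 1, seq)
  }
}

#' @rdname read_fasta_ref
#' @param ref A [ref_seq].
#' @param width Line-wrap width.
#' @export
write_fasta_ref <- function(ref, path, width = 70L) {
  stopifnot(inherits(ref, "ref_seq"))
  hdr <- sprintf(">%s:%d-%d", ref$chrom, ref$start, ref$start + nchar(ref$seq) - 1)
  n <- nchar(ref$seq)
  starts <- seq(1L, n, by = width)
  writeLines(c(hdr, substring(ref$seq, starts, pmin(starts + width - 1L, n))), path)
  invisible(path)
}
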