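#' Read a GT-only VCF subset into a cohort table
#'
#' Parses the VCF v4.2 subset every stage of the pipeline exchanges: meta
#' headers, the `#CHROM` header line, and body rows whose FORMAT begins with
#' `GT`. Diploid genotypes are converted to alternate-allele counts;
#' multi-allelic rows are split into one biallelic record per ALT (the rarity
#' classification and repeat calling are per-allele); `./.` (or any genotype
#' containing `.`) becomes missing. Case/control labels are not part of VCF;
#' they are supplied via `group` or default to `"case"` and can be reassigned
#' later.
#'
#' @param path VCF file path.
#' @param group Optional per-sample labels (`"case"`/`"control"`), recycled in
#'   sample order; default all `"case"`.
#' @return A [cohort_variants] object.
#' @export
read_vcf_lite <- function(path, group = NULL) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM\t", lines)
  if (length(hdr_i) != 1L) {
    stop_input("malformed VCF '%s': expected exactly one #CHROM header line", path)
  }
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  fixed_cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT")
  if (length(hdr) < 10L || !identical(hdr[1:9], fixed_cols)) {
    stop_input("malformed VCF header at line %d: need columns %s + samples",
               hdr_i, paste(fixed_cols, collapse = "/"))
  }
  samples <- hdr[-(1:9)]
  if (anyDuplicated(samples)) {
    stop_input("duplicate sample id '%s' in VCF header (line %d)",
               samples[duplicated(samples)][1], hdr_i)
  }
  body_i <- which(seq_along(lines) > hdr_i & nzchar(lines) & !startsWith(lines, "#"))

  chrom <- character(); pos <- numeric(); id <- character()
  ref <- character(); alt <- character(); geno <- list()
  for (i in body_i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + length(samples)) {
      stop_input("VCF parse error at line %d: %d fields, expected %d",
                 i, length(f), 9L + length(samples))
    }
    if (!startsWith(f[9], "GT")) {
      stop_input("VCF parse error at line %d: FORMAT must begin with GT", i)
    }
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    gt <- sub(":.*$", "", f[-(1:9)])
    al <- strsplit(gt, "[/|]")
    bad <- vapply(al, function(a) {
      length(a) != 2L || any(!grepl("^(\\.|[0-9]+)$", a))
    }, logical(1))
    if (any(bad)) {
      stop_input("VCF parse error at line %d: malformed GT '%s'",
                 i, gt[which(bad)[1]])
    }
    for (j in seq_along(alts)) {
      counts <- vapply(al, function(a) {
        if (any(a == ".")) return(NA_integer_)
        a <- as.integer(a)
        if (any(a > length(alts))) {
          stop_input("VCF parse error at line %d: GT allele index exceeds ALT count", i)
        }
        sum(a == j)
      }, integer(1))
      chrom <- c(chrom, f[1]); pos <- c(pos, as.numeric(f[2]))
      id <- c(id, f[3]); ref <- c(ref, f[4]); alt <- c(alt, alts[j])
      geno[[length(geno) + 1L]] <- counts
    }
  }
  variants <- data.frame(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  gm <- if (length(geno)) do.call(rbind, geno) else
    matrix(integer(), 0L, length(samples))
  if (is.null(group)) group <- rep("case", length(samples))
  cohort_variants(variants, samples, rep(group, length.out = length(samples)), gm)
}

#' Write a cohort table as a GT-only VCF
#'
#' Inverse of [read_vcf_lite()]: `read_vcf_lite(write_vcf_lite(x, f))`
#' reproduces `x` up to group labels (which VCF does not carry).
#'
#' @param cohort A [cohort_variants] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_lite <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_variants"))
  v <- cohort$variants
  gm <- cohort$genotypes
  gt <- function(counts) {
    out <- character(length(counts))
    out[is.na(counts)] <- "./."
    out[!is.na(counts) & counts == 0L] <- "0/0"
    out[!is.na(counts) & counts == 1L] <- "0/1"
    out[!is.na(counts) & counts == 2L] <- "1/1"
    out
  }
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], format(v$pos[i], scientific = FALSE), v$id[i],
            v$ref[i], v$alt[i], ".", "PASS", ".", "GT", gt(gm[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", cohort$samples), collapse = "\t"),
               rows),
             path)
  invisible(path)
}
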