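#' Create a variant record
#'
#' A single biallelic variant in VCF-style representation: `pos` is the 1-based
#' position of the first REF base. Multi-allelic sites are always split into
#' one record per ALT allele before any downstream counting.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position of the first REF base.
#' @param ref,alt REF and ALT allele strings over A/C/G/T; must differ and be
#'   non-empty.
#' @param id Optional identifier (default `"."`).
#' @return An object of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alt, id = ".") {
  pos <- as.numeric(pos)
  if (is.na(pos) || pos < 1 || pos != floor(pos)) stop_input("`pos` must be an integer >= 1")
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (!nzchar(ref) || !nzchar(alt)) stop_input("ref and alt must be non-empty")
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
    stop_input("ref/alt must be over {A,C,G,T} (got %s>%s)", ref, alt)
  }
  if (ref == alt) stop_input("ref and alt must differ (got %s>%s at %s:%d)",
                             ref, alt, chrom, pos)
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt, id = id),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s\n", variant_key(x)))
  invisible(x)
}

#' Canonical key of a variant
#'
#' `chrom:pos:ref:alt` on the record as given. Keys are comparable across a
#' cohort and a frequency panel only after [normalize_variant()].
#'
#' @param v A `variant_record` (or list with the same fields).
#' @return A string key.
#' @export
variant_key <- function(v) sprintf("%s:%d:%s:%s", v$chrom, v$pos, v$ref, v$alt)

#' Cohort variant table
#'
#' Container pairing a variant list with a per-sample genotype matrix and
#' case/control labels. Genotypes are alternate-allele counts in
#' `{0, 1, 2, NA}`; `NA` (missing) genotypes never count an individual as a
#' carrier and never shrink group denominators.
#'
#' @param variants A data.frame with columns chrom, pos, id, ref, alt (one row
#'   per biallelic record).
#' @param samples Character vector of unique sample ids.
#' @param group Factor/character of `"case"`/`"control"` per sample.
#' @param genotypes Integer matrix `length(variants) x length(samples)` of
#'   alt-allele counts (0/1/2/NA).
#' @return An object of class `cohort_variants`.
#' @export
cohort_variants <- function(variants, samples, group, genotypes) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop_input("`variants` must have columns %s", paste(need, collapse = ", "))
  }
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop_input("duplicate sample id: %s", samples[duplicated(samples)][1])
  }
  group <- as.character(group)
  if (length(group) != length(samples)) stop_input("one group label per sample required")
  if (!all(group %in% c("case", "control"))) {
    stop_input("group labels must be 'case' or 'control'")
  }
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(variants) || ncol(genotypes) != length(samples)) {
    stop_input("genotype matrix must be %d x %d (got %d x %d)",
               nrow(variants), length(samples), nrow(genotypes), ncol(genotypes))
  }
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok)) stop_input("genotypes must be allele counts in {0,1,2} or NA")
  rownames(genotypes) <- vkeys(variants)
  colnames(genotypes) <- samples
  structure(list(variants = variants, samples = samples,
                 group = stats::setNames(group, samples),
                 genotypes = genotypes),
            class = "cohort_variants")
}

vkeys <- function(variants) {
  sprintf("%s:%d:%s:%s", variants$chrom, as.integer(variants$pos),
          variants$ref, variants$alt)
}

#' @export
print.cohort_variants <- function(x, ...) {
  g <- table(factor(x$group, levels = c("case", "control")))
  cat(sprintf("<cohort_variants> %d variants x %d samples (%d case, %d control)\n",
              nrow(x$variants), length(x$samples), g[["case"]], g[["control"]]))
  invisible(x)
}

#' Reference-panel allele frequencies
#'
#' A named numeric vector mapping normalized variant keys
#' (`chrom:pos:ref:alt`) to population allele frequencies in `[0, 1]`,
#' emulating a summary-statistics panel such as a national biobank WGS
#' reference.
#'
#' @param keys Character vector of normalized variant keys.
#' @param af Numeric allele frequencies in `[0, 1]`.
#' @return A named numeric vector of class `panel_frequencies`.
#' @export
panel_frequencies <- function(keys, af) {
  af <- as.numeric(af)
  if (length(keys) != length(af)) stop_input("keys and af lengths differ")
  if (anyNA(af) || any(af < 0 | af > 1)) stop_input("allele frequencies must be in [0,1]")
  if (anyDuplicated(keys)) stop_input("duplicate panel key: %s", keys[duplicated(keys)][1])
  structure(stats::setNames(af, keys), class = "panel_frequencies")
}

#' Read / write a panel-frequency TSV (columns: key, af)
#' @param path File path.
#' @return `read_panel` returns a `panel_frequencies`; `write_panel` its input,
#'   invisibly.
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("key", "af") %in% names(df))) stop_input("panel TSV needs columns key, af")
  panel_frequencies(df$key, df$af)
}

#' @rdname read_panel
#' @param panel A `panel_frequencies` object.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(key = names(panel), af = as.numeric(panel))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panel)
}
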