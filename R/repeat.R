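#' Microsatellite locus definition
#'
#' The reference repeat run: a perfect tandem tract of `unit` repeated
#' `ref_units` times. The unit must not be self-periodic (no proper rotation
#' period), which guarantees perfect runs in different phases cannot overlap
#' and maximal-run counting is unambiguous.
#'
#' @param chrom Chromosome name.
#' @param tract A [genomic_interval] spanning the reference tract; its length
#'   must equal `ref_units * nchar(unit)`.
#' @param unit Repeat unit (default `"TTTG"`).
#' @param ref_units Reference copy number (default 4).
#' @param flank Scope window in bases around the tract within which variants
#'   are interpreted (default 100).
#' @return An object of class `repeat_locus`.
#' @examples
#' repeat_locus("chr15", genomic_interval("chr15", 88569434, 88569449))
#' @export
repeat_locus <- function(chrom, tract, unit = "TTTG", ref_units = 4L, flank = 100L) {
  stopifnot(inherits(tract, "genomic_interval"))
  unit <- toupper(unit)
  if (grepl("[^ACGT]", unit) || nchar(unit) < 1L) stop_input("unit must be a DNA string")
  if (interval_length(tract) != ref_units * nchar(unit)) {
    stop_input("tract length %d != ref_units (%d) x unit length (%d)",
               interval_length(tract), ref_units, nchar(unit))
  }
  if (is_self_periodic(unit)) stop_input("unit '%s' is self-periodic", unit)
  structure(list(chrom = chrom, tract = tract, unit = unit,
                 ref_units = as.integer(ref_units), flank = as.integer(flank)),
            class = "repeat_locus")
}

is_self_periodic <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n - 1)) {
    if (n %% p == 0 &&
        unit == paste(rep(substr(unit, 1, p), n / p), collapse = "")) {
      return(TRUE)
    }
  }
  FALSE
}

#' Normalize a variant to its parsimonious left-aligned form
#'
#' Indel representation inside a repeat is ambiguous: the same deletion can be
#' written at any equivalent offset. This produces the canonical form used as
#' the variant key everywhere: trim the shared suffix (extending left through
#' the reference when an allele would empty), left-shift as far as the sequence
#' allows, then trim the shared prefix down to the minimal representation with
#' at least one base per allele for indels.
#'
#' @param ref A [ref_seq] covering the variant.
#' @param variant A [variant_record] consistent with `ref`.
#' @return The normalized [variant_record].
#' @export
normalize_variant <- function(ref, variant) {
  stopifnot(inherits(ref, "ref_seq"), inherits(variant, "variant_record"))
  pos <- variant$pos; r <- variant$ref; a <- variant$alt
  obs <- ref_base_at(ref, pos, nchar(r))
  if (obs != r) {
    stop_input("REF mismatch at %s:%d: variant says '%s', reference has '%s'",
               variant$chrom, pos, r, obs)
  }
  last <- function(s) substr(s, nchar(s), nchar(s))
  # trim shared suffix, borrowing a left base when an allele would empty
  repeat {
    if (nchar(r) > 0 && nchar(a) > 0 && last(r) == last(a)) {
      if (nchar(r) == 1L && nchar(a) == 1L) break
      if (nchar(r) == 1L || nchar(a) == 1L) {
        if (pos <= ref$start) break  # cannot extend further left
        pos <- pos - 1
        b <- ref_base_at(ref, pos)
        r <- paste0(b, substr(r, 1, nchar(r) - 1))
        a <- paste0(b, substr(a, 1, nchar(a) - 1))
      } else {
        r <- substr(r, 1, nchar(r) - 1)
        a <- substr(a, 1, nchar(a) - 1)
      }
    } else break
  }
  # trim shared prefix to minimal form (>= 1 base each)
  while (nchar(r) > 1L && nchar(a) > 1L &&
         substr(r, 1, 1) == substr(a, 1, 1)) {
    r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a))
    pos <- pos + 1
  }
  variant_record(variant$chrom, pos, r, a, variant$id)
}

#' Locate the maximal perfect repeat run at an anchor
#'
#' Scans all phases of `unit` and returns the maximal run of perfect tandem
#' copies whose span contains `anchor_pos`. Interrupted tracts report the
#' maximal perfect run only; the classifier, not the count, carries the
#' interpretation of an internal substitution.
#'
#' @param ref A [ref_seq] (or plain string, then coordinates are string
#'   offsets).
#' @param unit Repeat unit.
#' @param anchor_pos 1-based position the run must contain.
#' @return List with `tract` (a [genomic_interval], or `NULL` when no copy of
#'   the unit covers the anchor) and `unit_count` (0 in that case).
#' @export
find_repeat_tract <- function(ref, unit, anchor_pos) {
  if (is.character(ref)) ref <- ref_seq("seq", 1, ref)
  stopifnot(inherits(ref, "ref_seq"))
  unit <- toupper(unit)
  off <- ref_offset(ref, anchor_pos)
  m <- gregexpr(sprintf("(?:%s)+", unit), ref$seq)[[1]]
  if (m[1] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    hit <- which(starts <= off & off <= starts + lens - 1L)
    if (length(hit) == 1L) {
      s <- starts[hit]; l <- lens[hit]
      return(list(
        tract = genomic_interval(ref$chrom, ref$start + s - 1,
                                 ref$start + s + l - 2),
        unit_count = l %/% nchar(unit)
      ))
    }
  }
  list(tract = NULL, unit_count = 0L)
}

# apply a (normalized) variant to an anchored reference; returns the alternate
# sequence as a ref_seq with the same genomic start
apply_variant <- function(ref, variant) {
  off <- ref_offset(ref, variant$pos)
  obs <- substr(ref$seq, off, off + nchar(variant$ref) - 1L)
  if (obs != variant$ref) {
    stop_input("REF mismatch at %s:%d: variant says '%s', reference has '%s'",
               variant$chrom, variant$pos, variant$ref, obs)
  }
  ref_seq(ref$chrom, ref$start,
          paste0(substr(ref$seq, 1, off - 1L), variant$alt,
                 substr(ref$seq, off + nchar(variant$ref), nchar(ref$seq))))
}

repeat_call <- function(allele_class, unit_count = NA_integer_,
                        disrupting_change = NULL) {
  structure(list(allele_class = allele_class,
                 unit_count = if (is.na(unit_count)) NA_integer_ else as.integer(unit_count),
                 disrupting_change = disrupting_change),
            class = "repeat_call")
}

#' @export
print.repeat_call <- function(x, ...) {
  cat(sprintf("<repeat_call> %s%s\n", x$allele_class,
              if (!is.na(x$unit_count)) sprintf(" (unit_count=%d)", x$unit_count) else ""))
  invisible(x)
}

#' Classify one variant allele at the microsatellite locus
#'
#' Applies the variant to the reference, re-locates the repeat tract on the
#' alternate sequence, and classifies the allele:
#' `UNIT_LOSS`/`UNIT_GAIN` for a pure unit-multiple length change confined to
#' the tract (with the new copy number), `SNV_DISRUPTED` for a single-base
#' substitution inside the tract that breaks a unit without changing length,
#' `OTHER` for anything else in scope, and `OUT_OF_SCOPE` (not an error) for
#' variants beyond the locus flank window.
#'
#' @param locus A [repeat_locus].
#' @param ref A [ref_seq] carrying the reference tract.
#' @param variant A [variant_record]; normalized internally.
#' @return A `repeat_call`.
#' @examples
#' ref <- make_repeat_locus_reference(flank_length = 60, n_units = 4, seed = 1)
#' loc <- attr(ref, "locus")
#' del <- variant_record(loc$chrom, loc$tract$start - 1,
#'                       ref_base_at(ref, loc$tract$start - 1, 5),
#'                       ref_base_at(ref, loc$tract$start - 1, 1))
#' call_repeat_allele(loc, ref, del)  # UNIT_LOSS, unit_count 3
#' @export
call_repeat_allele <- function(locus, ref, variant) {
  stopifnot(inherits(locus, "repeat_locus"), inherits(ref, "ref_seq"),
            inherits(variant, "variant_record"))
  v <- normalize_variant(ref, variant)
  tract <- locus$tract
  v_last_ref <- v$pos + nchar(v$ref) - 1
  in_scope <- v$chrom == locus$chrom &&
    v_last_ref >= tract$start - locus$flank &&
    v$pos <= tract$end + locus$flank
  if (!in_scope) return(repeat_call("OUT_OF_SCOPE"))

  alt_ref <- apply_variant(ref, v)
  len_change <- nchar(v$alt) - nchar(v$ref)
  # anchor the tract search at the (possibly shifted) tract start
  anchor <- if (v_last_ref < tract$start) tract$start + len_change else tract$start
  anchor <- min(max(anchor, alt_ref$start), alt_ref$start + nchar(alt_ref$seq) - 1)
  found <- find_repeat_tract(alt_ref, locus$unit, anchor)
  new_count <- found$unit_count

  ulen <- nchar(locus$unit)
  if (len_change != 0 && len_change %% ulen == 0) {
    expected <- locus$ref_units + len_change %/% ulen
    if (expected >= 0) {
      # representation-invariant confinement test: the alternate sequence must
      # equal the reference with the tract resized to `expected` copies
      t_off <- ref_offset(ref, tract$start)
      t_end <- ref_offset(ref, tract$end)
      ideal <- paste0(substr(ref$seq, 1, t_off - 1L),
                      strrep(locus$unit, expected),
                      substr(ref$seq, t_end + 1L, nchar(ref$seq)))
      if (alt_ref$seq == ideal) {
        cls <- if (len_change < 0) "UNIT_LOSS" else "UNIT_GAIN"
        return(repeat_call(cls, expected))
      }
    }
  }
  if (nchar(v$ref) == 1L && nchar(v$alt) == 1L &&
      v$pos >= tract$start && v$pos <= tract$end && new_count < locus$ref_units) {
    return(repeat_call("SNV_DISRUPTED", new_count, disrupting_change = v))
  }
  repeat_call("OTHER", new_count)
}

#' Genotype one sample's microsatellite diplotype
#'
#' Combines a sample's in-scope variants into one repeat call per haplotype.
#' No variant gives `(REF, REF)`; a heterozygous variant `(REF, call)`; a
#' homozygous variant `(call, call)`. More than one in-scope variant per
#' haplotype cannot be resolved without phase and yields an `AMBIGUOUS`
#' diplotype.
#'
#' @param locus A [repeat_locus].
#' @param ref A [ref_seq].
#' @param sample_variants List of [variant_record]s observed in the sample.
#' @param counts Integer alt-allele counts (1 = het, 2 = hom) aligned with
#'   `sample_variants`.
#' @return List of two `repeat_call`s (class `repeat_diplotype`).
#' @export
genotype_sample <- function(locus, ref, sample_variants, counts) {
  stopifnot(length(sample_variants) == length(counts))
  keep <- which(counts > 0)
  calls <- list(); cnt <- integer(0)
  for (i in keep) {
    cl <- call_repeat_allele(locus, ref, sample_variants[[i]])
    if (cl$allele_class != "OUT_OF_SCOPE") {
      calls[[length(calls) + 1L]] <- cl
      cnt <- c(cnt, counts[i])
    }
  }
  dip <- if (length(calls) == 0L) {
    list(repeat_call("REF", locus$ref_units), repeat_call("REF", locus$ref_units))
  } else if (length(calls) == 1L && cnt == 1L) {
    list(repeat_call("REF", locus$ref_units), calls[[1]])
  } else if (length(calls) == 1L && cnt == 2L) {
    list(calls[[1]], calls[[1]])
  } else {
    list(repeat_call("AMBIGUOUS"), repeat_call("AMBIGUOUS"))
  }
  structure(dip, class = "repeat_diplotype")
}

#' @export
print.repeat_diplotype <- function(x, ...) {
  fmt <- function(cl) if (!is.na(cl$unit_count)) {
    sprintf("%s(%d)", cl$allele_class, cl$unit_count)
  } else cl$allele_class
  cat(sprintf("<repeat_diplotype> %s / %s\n", fmt(x[[1]]), fmt(x[[2]])))
  invisible(x)
}
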