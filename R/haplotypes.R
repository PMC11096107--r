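#' Marker panel for haplotype segregation analysis
#'
#' Ordered STR/SNP markers flanking a focal variant, as used to test whether
#' independently ascertained carrier families share a founder haplotype.
#'
#' @param name Marker names.
#' @param type `"STR"` or `"SNP"` per marker.
#' @param position 1-based genomic positions, strictly increasing.
#' @param freqs List of per-marker allele-frequency vectors (alleles are the
#'   integer codes `1..length(freqs[[i]])`).
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(name, type, position, freqs) {
  n <- length(name)
  if (n < 1L) stop_input("panel needs >= 1 marker")
  type <- rep(type, length.out = n)
  if (!all(type %in% c("STR", "SNP"))) stop_input("marker type must be STR or SNP")
  position <- as.numeric(position)
  if (any(diff(position) <= 0)) stop_input("marker positions must be strictly increasing")
  if (length(freqs) != n) stop_input("one frequency vector per marker required")
  for (f in freqs) {
    if (any(f <= 0) || abs(sum(f) - 1) > 1e-8) stop_input("allele frequencies must be positive and sum to 1")
  }
  structure(list(name = name, type = type, position = position, freqs = freqs,
                 n = n), class = "marker_panel")
}

get_marker_genotypes <- function(ped, genotypes) {
  if (is.null(genotypes)) genotypes <- ped$markers
  if (length(genotypes) == 0L) stop_input("no marker genotypes available")
  genotypes
}

#' Mendelian-consistency check across a marker panel
#'
#' A violation is recorded when a child's unordered allele pair cannot be
#' formed by taking one allele from each genotyped parent. A missing genotype
#' in the child or either parent makes the marker unjudgeable — never a
#' violation.
#'
#' @param ped A [pedigree].
#' @param genotypes Named list of `n x 2` allele matrices; defaults to
#'   `ped$markers`.
#' @return data.frame with columns `individual`, `marker` (zero rows when
#'   clean).
#' @export
check_mendelian <- function(ped, genotypes = NULL) {
  genotypes <- get_marker_genotypes(ped, genotypes)
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  out <- list()
  for (mk in names(genotypes)) {
    g <- genotypes[[mk]]
    for (i in which(!is.na(fa))) {
      child <- g[i, ]; pf <- g[fa[i], ]; pm <- g[mo[i], ]
      if (anyNA(child) || anyNA(pf) || anyNA(pm)) next
      ok <- (child[1] %in% pf && child[2] %in% pm) ||
            (child[2] %in% pf && child[1] %in% pm)
      if (!ok) out[[length(out) + 1L]] <- data.frame(individual = ped$id[i],
                                                     marker = mk,
                                                     stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(individual = character(0), marker = character(0)))
  }
  do.call(rbind, out)
}

#' De novo detection for the focal variant
#'
#' For each child with both parents in the pedigree, classifies the child's
#' carrier status as `"transmitted"` (a carrier parent exists), `"de_novo"`
#' (carrier child, both parents genotyped non-carriers, zero Mendelian
#' violations across the marker panel supporting true parentage),
#' `"parentage_questioned"` (as de novo but with marker violations),
#' `"indeterminate"` (a parent ungenotyped for the variant), or
#' `"non_carrier"`.
#'
#' @param ped A [pedigree].
#' @param carrier_status Logical vector (one per individual, `NA` =
#'   ungenotyped for the focal variant).
#' @param genotypes Marker genotypes as in [check_mendelian()].
#' @return data.frame with columns `individual`, `status`.
#' @export
detect_de_novo <- function(ped, carrier_status, genotypes = NULL) {
  if (length(carrier_status) != ped$n) stop_input("one carrier status per individual required")
  genotypes <- get_marker_genotypes(ped, genotypes)
  viol <- check_mendelian(ped, genotypes)
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  rows <- lapply(which(!is.na(fa)), function(i) {
    status <- if (!isTRUE(carrier_status[i])) {
      "non_carrier"
    } else if (is.na(carrier_status[fa[i]]) || is.na(carrier_status[mo[i]])) {
      "indeterminate"
    } else if (carrier_status[fa[i]] || carrier_status[mo[i]]) {
      "transmitted"
    } else if (ped$id[i] %in% viol$individual) {
      "parentage_questioned"
    } else {
      "de_novo"
    }
    data.frame(individual = ped$id[i], status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Phase the carrier haplotype of one family
#'
#' Rule-based transmission phasing of the chromosome bearing the focal
#' variant. Evidence per marker: (i) in every carrier-parent to carrier-child
#' meiosis, the allele the carrier parent transmitted (unique by subtraction
#' of the other parent's contribution; recombination is not modelled in the
#' small marker window); (ii) any carrier's homozygous genotype. Contradictory
#' evidence (recombination or genotyping error) sets the marker to missing and
#' logs a conflict; uninformative markers stay missing.
#'
#' @param ped A single-family [pedigree].
#' @param carrier_status Logical per individual (`NA` = ungenotyped).
#' @param genotypes Marker genotypes as in [check_mendelian()].
#' @return An object of class `carrier_haplotype`: `family`, `alleles` (named
#'   integer vector, `NA` = unphased), `completeness`, and a `conflicts`
#'   attribute naming markers with contradictory evidence.
#' @export
phase_carriers <- function(ped, carrier_status, genotypes = NULL) {
  if (length(unique(ped$family)) != 1L) stop_input("phase one family at a time")
  if (length(carrier_status) != ped$n) stop_input("one carrier status per individual required")
  genotypes <- get_marker_genotypes(ped, genotypes)
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  carriers <- which(isTRUE_v(carrier_status))
  if (length(carriers) == 0L) stop_input("family has no genotyped carrier")
  # carrier parent -> carrier child meioses
  meioses <- list()
  for (i in which(!is.na(fa))) {
    if (!isTRUE(carrier_status[i])) next
    for (p in c(fa[i], mo[i])) {
      if (isTRUE(carrier_status[p])) {
        other <- if (p == fa[i]) mo[i] else fa[i]
        meioses[[length(meioses) + 1L]] <- c(parent = p, child = i, other = other)
      }
    }
  }
  alleles <- stats::setNames(rep(NA_integer_, length(genotypes)), names(genotypes))
  conflicts <- character(0)
  for (mi in seq_along(genotypes)) {
    g <- genotypes[[mi]]
    evidence <- integer(0)
    for (me in meioses) {
      tr <- transmitted_allele(g[me["parent"], ], g[me["child"], ], g[me["other"], ])
      if (!is.na(tr)) evidence <- c(evidence, tr)
    }
    for (ci in carriers) {
      gc <- g[ci, ]
      if (!anyNA(gc) && gc[1] == gc[2]) evidence <- c(evidence, gc[1])
    }
    if (length(evidence) > 0L) {
      if (length(unique(evidence)) == 1L) {
        alleles[mi] <- evidence[1]
      } else {
        conflicts <- c(conflicts, names(genotypes)[mi])
      }
    }
  }
  structure(list(family = ped$family[1], alleles = alleles,
                 completeness = mean(!is.na(alleles))),
            conflicts = conflicts, class = "carrier_haplotype")
}

isTRUE_v <- function(x) !is.na(x) & x

# allele transmitted from `parent` to `child`, using `other` parent's genotype
# to resolve which child allele came from where; NA when uninformative
transmitted_allele <- function(parent, child, other) {
  if (anyNA(parent) || anyNA(child)) return(NA_integer_)
  if (parent[1] == parent[2]) {
    if (parent[1] %in% child) return(parent[1])
    return(NA_integer_)  # Mendelian conflict at this meiosis; not resolvable here
  }
  cand <- integer(0)
  for (j in 1:2) {
    x <- child[j]; y <- child[3 - j]
    if (!(x %in% parent)) next
    ok_other <- anyNA(other) || y %in% other
    if (ok_other) cand <- c(cand, x)
  }
  cand <- unique(cand)
  if (length(cand) == 1L) cand else NA_integer_
}

#' @export
print.carrier_haplotype <- function(x, ...) {
  cat(sprintf("<carrier_haplotype> family %s: [%s] (completeness %.2f)\n",
              x$family,
              paste(ifelse(is.na(x$alleles), ".", x$alleles), collapse = " "),
              x$completeness))
  invisible(x)
}

#' Count distinct founder haplotypes across carrier families
#'
#' Families are grouped by exact match on jointly non-missing marker alleles
#' (two haplotypes that disagree at no commonly phased marker fall in one
#' group). Because missing data can only merge groups, the returned `k` is a
#' conservative lower bound — "at least k" founder chromosomes.
#'
#' @param haplotypes List of [phase_carriers()] results over a common panel.
#' @param min_completeness Haplotypes below this completeness are excluded
#'   from the count (default 0.5).
#' @return List with `k`, `groups` (assignment per retained haplotype, named
#'   by family) and `excluded` (families dropped for low completeness).
#' @export
count_founder_haplotypes <- function(haplotypes, min_completeness = 0.5) {
  if (length(haplotypes) == 0L) {
    return(list(k = 0L, groups = integer(0), excluded = character(0)))
  }
  stopifnot(all(vapply(haplotypes, inherits, logical(1), "carrier_haplotype")))
  nm <- vapply(haplotypes, function(h) h$family, character(1))
  comp <- vapply(haplotypes, function(h) h$completeness, numeric(1))
  keep <- comp >= min_completeness
  hs <- haplotypes[keep]
  compatible <- function(a, b) {
    both <- !is.na(a$alleles) & !is.na(b$alleles)
    all(a$alleles[both] == b$alleles[both])
  }
  groups <- integer(length(hs))
  reps <- list()  # members per group
  for (i in seq_along(hs)) {
    placed <- FALSE
    for (gidx in seq_along(reps)) {
      if (all(vapply(reps[[gidx]], compatible, logical(1), b = hs[[i]]))) {
        groups[i] <- gidx
        reps[[gidx]] <- c(reps[[gidx]], list(hs[[i]]))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- list(hs[[i]])
      groups[i] <- length(reps)
    }
  }
  list(k = length(reps), groups = stats::setNames(groups, nm[keep]),
       excluded = nm[!keep])
}
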