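#' Pedigree container
#'
#' Individuals with parent links, sex, affection status and optional marker
#' genotypes (unordered allele pairs; `NA` = untyped). Founders have both
#' parent links `NA`; non-founders must have both parents present in the same
#' family. The structure must be acyclic (no individual its own ancestor).
#'
#' @param family Family id (recycled if length 1).
#' @param id Individual ids, unique within family.
#' @param father,mother Parent ids or `NA` (founder). `0`/`"0"` is accepted as
#'   the PED missing code.
#' @param sex Codes `1` (male), `2` (female), `0`/`NA` (unknown).
#' @param affection `"affected"`, `"unaffected"` or `"unknown"` (PED codes
#'   2/1/0 also accepted).
#' @param markers Named list of `n x 2` matrices of integer allele codes
#'   (`NA` = missing), one per marker.
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(family, id, father, mother, sex,
                     affection = "unknown", markers = list()) {
  n <- length(id)
  family <- as.character(rep(family, length.out = n))
  id <- as.character(id)
  to_na <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA_character_
    x
  }
  father <- to_na(rep(father, length.out = n))
  mother <- to_na(rep(mother, length.out = n))
  sex <- as.integer(rep(sex, length.out = n))
  sex[is.na(sex) | !sex %in% 1:2] <- 0L
  aff <- as.character(rep(affection, length.out = n))
  aff[aff == "2"] <- "affected"; aff[aff == "1"] <- "unaffected"
  aff[aff == "0"] <- "unknown"
  if (!all(aff %in% c("affected", "unaffected", "unknown"))) {
    stop_input("affection must be affected/unaffected/unknown (PED 2/1/0)")
  }
  key <- paste(family, id)
  if (anyDuplicated(key)) stop_input("duplicate individual id within family: %s",
                                     id[duplicated(key)][1])
  if (xor_any <- any(is.na(father) != is.na(mother))) {
    stop_input("individual '%s' has exactly one parent recorded; need both or none",
               id[is.na(father) != is.na(mother)][1])
  }
  # parent links must resolve within the same family
  for (i in seq_len(n)) {
    for (p in c(father[i], mother[i])) {
      if (!is.na(p) && !any(id == p & family == family[i])) {
        stop_input("link error: parent '%s' of individual '%s' absent from family '%s'",
                   p, id[i], family[i])
      }
    }
  }
  ped <- structure(list(family = family, id = id, father = father,
                        mother = mother, sex = sex, affection = aff,
                        markers = validate_markers(markers, n), n = n),
                   class = "pedigree")
  check_acyclic(ped)
  ped
}

validate_markers <- function(markers, n) {
  if (length(markers) == 0L) return(list())
  if (is.null(names(markers)) || any(!nzchar(names(markers)))) {
    names(markers) <- sprintf("M%d", seq_along(markers))
  }
  lapply(markers, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != 2L) stop_input("each marker must be an n x 2 matrix")
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m[!is.na(m) & m == 0L] <- NA_integer_
    m
  })
}

check_acyclic <- function(ped) {
  idx <- function(fam, id) which(ped$family == fam & ped$id == id)
  state <- integer(ped$n)  # 0 unvisited, 1 in progress, 2 done
  visit <- function(i) {
    if (state[i] == 1L) {
      stop_input("cycle error: individual '%s' is its own ancestor", ped$id[i])
    }
    if (state[i] == 2L) return(invisible())
    state[i] <<- 1L
    for (p in c(ped$father[i], ped$mother[i])) {
      if (!is.na(p)) visit(idx(ped$family[i], p))
    }
    state[i] <<- 2L
  }
  for (i in seq_len(ped$n)) visit(i)
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals in %d family(ies); %d founder(s), %d affected; %d marker(s)\n",
              x$n, length(unique(x$family)), sum(is_founder(x)),
              sum(x$affection == "affected"), length(x$markers)))
  invisible(x)
}

#' Founder indicator
#' @param ped A `pedigree`.
#' @return Logical vector, `TRUE` where both parents are missing.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' Split a multi-family pedigree into one object per family
#' @param ped A `pedigree`.
#' @return Named list of single-family `pedigree` objects.
#' @export
split_families <- function(ped) {
  fams <- unique(ped$family)
  out <- lapply(fams, function(f) {
    sel <- ped$family == f
    pedigree(ped$family[sel], ped$id[sel], ped$father[sel], ped$mother[sel],
             ped$sex[sel], ped$affection[sel],
             lapply(ped$markers, function(m) m[sel, , drop = FALSE]))
  })
  stats::setNames(out, fams)
}

#' Read a LINKAGE pre-makeped PED file
#'
#' Whitespace-delimited columns: family, individual, father, mother, sex
#' (1/2/0), phenotype (2 = affected, 1 = unaffected, 0 = unknown), then one
#' pair of integer allele columns per marker (0 = missing).
#'
#' @param path PED file path.
#' @param marker_names Optional names for the marker columns.
#' @return A [pedigree] (possibly multi-family).
#' @export
read_ped <- function(path, marker_names = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6L) stop_input("PED file '%s' needs >= 6 columns", path)
  extra <- ncol(df) - 6L
  if (extra %% 2L != 0L) {
    stop_input("PED file '%s': marker columns must come in allele pairs", path)
  }
  n_mark <- extra %/% 2L
  markers <- list()
  if (n_mark > 0L) {
    if (is.null(marker_names)) marker_names <- sprintf("M%d", seq_len(n_mark))
    for (k in seq_len(n_mark)) {
      a1 <- suppressWarnings(as.integer(df[[6L + 2L * k - 1L]]))
      a2 <- suppressWarnings(as.integer(df[[6L + 2L * k]]))
      markers[[marker_names[k]]] <- cbind(a1, a2)
    }
  }
  pedigree(df[[1]], df[[2]], df[[3]], df[[4]], df[[5]], df[[6]], markers)
}

#' Write a pedigree as a LINKAGE pre-makeped PED file
#' @param ped A [pedigree].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  aff_code <- c(affected = "2", unaffected = "1", unknown = "0")[ped$affection]
  cols <- list(ped$family, ped$id,
               ifelse(is.na(ped$father), "0", ped$father),
               ifelse(is.na(ped$mother), "0", ped$mother),
               as.character(ped$sex), aff_code)
  for (m in ped$markers) {
    m0 <- m; m0[is.na(m0)] <- 0L
    cols <- c(cols, list(as.character(m0[, 1]), as.character(m0[, 2])))
  }
  writeLines(do.call(paste, cols), path)
  invisible(path)
}
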