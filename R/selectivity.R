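#' Median binned depth of a coverage track over a region
#'
#' Median of the fixed-width bin depths whose bins overlap `region`. Bins are
#' anchored at the track's declared interval start; bins partially overlapping
#' the region are included whole (no re-weighting), matching a
#' precomputed-bins workflow. Even bin counts take the midpoint of the two
#' central values.
#'
#' @param track A [coverage_track].
#' @param region A [genomic_interval] overlapping the track.
#' @return Median depth (numeric).
#' @export
region_median_depth <- function(track, region) {
  stopifnot(inherits(track, "coverage_track"), inherits(region, "genomic_interval"))
  iv <- track$interval
  if (!intervals_overlap(iv, region)) {
    stop_input("coverage error: region %s outside track %s",
               format_interval(region), format_interval(iv))
  }
  lo <- max(region$start, iv$start); hi <- min(region$end, iv$end)
  b1 <- (lo - iv$start) %/% track$bin_width + 1
  b2 <- (hi - iv$start) %/% track$bin_width + 1
  stats::median(track$depths[b1:b2])
}

#' Cell-type selectivity of chromatin accessibility over a region
#'
#' The published score: the target cell type's median binned read depth over
#' the region divided by the sum of all cell types' median depths over the
#' same region. Scores over all cell types sum to 1 whenever the sum of
#' medians is positive; an all-zero region is flagged undefined rather than
#' raising an error.
#'
#' @param tracks List of [coverage_track]s with unique cell-type names (>= 2).
#' @param region A [genomic_interval].
#' @param target_cell_type Name of the cell type of interest.
#' @return An object of class `selectivity_result`: `region`, `medians` (named
#'   per cell type), `selectivity` (named ratios; `NA` when undefined),
#'   `target_selectivity`, `undefined` flag.
#' @export
selectivity_score <- function(tracks, region, target_cell_type) {
  if (length(tracks) < 2L) stop_input("need >= 2 coverage tracks")
  stopifnot(all(vapply(tracks, inherits, logical(1), "coverage_track")))
  cts <- vapply(tracks, function(t) t$cell_type, character(1))
  if (anyDuplicated(cts)) {
    stop_input("duplicate cell-type name: %s", cts[duplicated(cts)][1])
  }
  if (!target_cell_type %in% cts) stop_input("unknown target cell type '%s'", target_cell_type)
  med <- vapply(tracks, region_median_depth, numeric(1), region = region)
  names(med) <- cts
  total <- sum(med)
  if (total > 0) {
    sel <- med / total
    undefined <- FALSE
  } else {
    sel <- stats::setNames(rep(NA_real_, length(med)), cts)
    undefined <- TRUE
  }
  structure(list(region = region, medians = med, selectivity = sel,
                 target_cell_type = target_cell_type,
                 target_selectivity = unname(sel[target_cell_type]),
                 undefined = undefined),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf("<selectivity_result> %s: target '%s' selectivity = %s (over %d cell types)\n",
              format_interval(x$region), x$target_cell_type,
              if (x$undefined) "undefined" else sprintf("%.6f", x$target_selectivity),
              length(x$medians)))
  invisible(x)
}

#' Rank regions by target cell-type selectivity
#'
#' Descending selectivity; ties broken by genomic position; regions with
#' undefined selectivity (zero total median) come last.
#'
#' @param tracks List of [coverage_track]s.
#' @param regions Non-empty list of [genomic_interval]s.
#' @param target_cell_type Cell type to rank by.
#' @return data.frame with columns `chrom`, `start`, `end`,
#'   `target_selectivity`, `undefined`, ordered best-first.
#' @export
rank_regions <- function(tracks, regions, target_cell_type) {
  if (length(regions) == 0L) stop_input("`regions` must be non-empty")
  rows <- lapply(regions, function(r) {
    s <- selectivity_score(tracks, r, target_cell_type)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               target_selectivity = ifelse(s$undefined, NA_real_, s$target_selectivity),
               undefined = s$undefined, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  o <- order(df$undefined, -ifelse(is.na(df$target_selectivity), -Inf,
                                   df$target_selectivity),
             df$chrom, df$start)
  df[o, , drop = FALSE]
}
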