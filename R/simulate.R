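#' Configuration for the synthetic case/control cohort
#'
#' Defaults emulate the published whole-genome screen: 25 patients and 56
#' controls scanned over the 3.2-Mb chr15 linkage region in 500-bp windows,
#' with a per-individual background of private rare variants whose overall
#' density matches the reported 2,446 rare variants across 81 participants
#' (~0.0094 per individual per kb), one spiked window at the bin containing
#' the microsatellite locus, and a strong case-restricted spike (the shared
#' deletion was seen in most unsolved families but no controls).
#'
#' @param region A [genomic_interval] (default chr15:86,206,001-89,412,500).
#' @param n_cases,n_controls Cohort sizes (defaults 25 and 56).
#' @param background_rare_rate Expected background rare variants per individual
#'   per kb (default 0.0094).
#' @param spiked_bin_index 1-based bin to spike, or `NA` for a null cohort
#'   (default: the bin containing position 88,569,434).
#' @param spike_carrier_fraction_cases,spike_carrier_fraction_controls
#'   Probability that a case/control individual carries the spiked variant
#'   (defaults 0.7 and 0).
#' @param rare_threshold Panel AF cutoff (default 0.002).
#' @param bin_width Window size used to place the spike (default 500).
#' @param panel_dropout Fraction of generated variants absent from the panel
#'   (absent variants are rare by definition; default 0.3).
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(region = genomic_interval("chr15", 86206001, 89412500),
                              n_cases = 25, n_controls = 56,
                              background_rare_rate = 0.0094,
                              spiked_bin_index = 4727L,
                              spike_carrier_fraction_cases = 0.7,
                              spike_carrier_fraction_controls = 0,
                              rare_threshold = 0.002, bin_width = 500,
                              panel_dropout = 0.3, seed = 1L) {
  stopifnot(inherits(region, "genomic_interval"))
  if (interval_length(region) < bin_width) {
    stop_input("region shorter than one bin")
  }
  for (p in c(spike_carrier_fraction_cases, spike_carrier_fraction_controls,
              panel_dropout)) {
    if (!(p >= 0 && p <= 1)) stop_input("carrier fractions must be in [0,1]")
  }
  if (background_rare_rate < 0) stop_input("`background_rare_rate` must be >= 0")
  n_bins <- length(make_bins(region, bin_width))
  if (!is.na(spiked_bin_index) &&
      (spiked_bin_index < 1 || spiked_bin_index > n_bins)) {
    stop_input("spiked bin %d outside region (%d bins)", spiked_bin_index, n_bins)
  }
  structure(list(region = region, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 background_rare_rate = background_rare_rate,
                 spiked_bin_index = spiked_bin_index,
                 spike_carrier_fraction_cases = spike_carrier_fraction_cases,
                 spike_carrier_fraction_controls = spike_carrier_fraction_controls,
                 rare_threshold = rare_threshold, bin_width = as.integer(bin_width),
                 panel_dropout = panel_dropout, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a case/control cohort with an optional spiked window
#'
#' Background rare variants are private (one heterozygous carrier each) and
#' placed uniformly over the region per individual at `background_rare_rate`;
#' the spiked window carries one shared 4-bp-deletion-style variant whose
#' carriers are drawn per group at the configured fractions. Panel allele
#' frequencies are drawn uniformly below `rare_threshold`, with a fraction of
#' variants absent from the panel entirely. Identical `(config, seed)` give
#' byte-identical output.
#'
#' @param config A [cohort_sim_config].
#' @return List with `cohort` ([cohort_variants]), `panel`
#'   ([panel_frequencies]) and `truth` (spiked bin, spiked variant key,
#'   carrier ids).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    region <- config$region
    n <- config$n_cases + config$n_controls
    samples <- c(sprintf("case%03d", seq_len(config$n_cases)),
                 sprintf("ctrl%03d", seq_len(config$n_controls)))
    group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
    lambda <- config$background_rare_rate * interval_length(region) / 1000

    carrier_of <- list(); pos_of <- numeric(0)
    for (i in seq_len(n)) {
      nv <- stats::rpois(1, lambda)
      if (nv == 0) next
      pos <- region$start + sample.int(interval_length(region), nv, replace = FALSE) - 1
      pos_of <- c(pos_of, pos)
      carrier_of <- c(carrier_of, rep(list(i), nv))
    }
    # deterministic ref/alt per position so coinciding draws merge into one record
    bases <- c("A", "C", "G", "T")
    upos <- sort(unique(pos_of))
    ref_b <- bases[(upos %% 4) + 1]
    alt_b <- bases[((upos + 1) %% 4) + 1]
    geno <- matrix(0L, nrow = length(upos), ncol = n)
    for (j in seq_along(pos_of)) {
      r <- match(pos_of[j], upos)
      geno[r, carrier_of[[j]]] <- pmin(2L, geno[r, carrier_of[[j]]] + 1L)
    }
    variants <- data.frame(chrom = rep(region$chrom, length(upos)), pos = upos,
                           id = rep(".", length(upos)), ref = ref_b, alt = alt_b,
                           stringsAsFactors = FALSE)

    truth <- list(spiked_bin_index = config$spiked_bin_index,
                  spike_key = NA_character_, case_carriers = character(0),
                  control_carriers = character(0),
                  bin_width = config$bin_width, n_bins = length(make_bins(region, config$bin_width)))
    if (!is.na(config$spiked_bin_index)) {
      bin_start <- region$start + (config$spiked_bin_index - 1) * config$bin_width
      spike_pos <- min(bin_start + config$bin_width %/% 2, region$end - 4)
      spike <- data.frame(chrom = region$chrom, pos = spike_pos, id = "spike",
                          ref = "CTTTG", alt = "C", stringsAsFactors = FALSE)
      carr <- c(stats::rbinom(config$n_cases, 1, config$spike_carrier_fraction_cases),
                stats::rbinom(config$n_controls, 1, config$spike_carrier_fraction_controls))
      variants <- rbind(variants, spike)
      geno <- rbind(geno, as.integer(carr))
      truth$spike_key <- sprintf("%s:%d:CTTTG:C", region$chrom, as.integer(spike_pos))
      truth$case_carriers <- samples[carr == 1 & group == "case"]
      truth$control_carriers <- samples[carr == 1 & group == "control"]
    }
    o <- order(variants$pos)
    variants <- variants[o, , drop = FALSE]
    geno <- geno[o, , drop = FALSE]
    cohort <- cohort_variants(variants, samples, group, geno)

    keys <- vkeys(variants)
    af <- stats::runif(length(keys), 0, config$rare_threshold)
    in_panel <- stats::runif(length(keys)) >= config$panel_dropout
    panel <- panel_frequencies(keys[in_panel], af[in_panel])
    list(cohort = cohort, panel = panel, truth = truth)
  })
}

#' Built-in pedigree templates for gene-dropping
#'
#' @param name `"trio"`, `"nuclear"` (two founders plus `n_children`), or
#'   `"threegen"` (a phase-informative three-generation family: affected
#'   grandparent couple, one carrier child, a married-in spouse and
#'   `n_children` grandchildren).
#' @param n_children Number of (grand)children where applicable (default 4).
#' @return A [pedigree] without genotypes or affection (all `"unknown"`).
#' @export
pedigree_template <- function(name = c("trio", "nuclear", "threegen"),
                              n_children = 4L) {
  name <- match.arg(name)
  if (!is_count(n_children) || n_children < 1) stop_input("`n_children` must be >= 1")
  if (name == "trio") n_children <- 1L
  if (name %in% c("trio", "nuclear")) {
    kid <- sprintf("c%d", seq_len(n_children))
    return(pedigree("fam1", c("p1", "p2", kid),
                    c(NA, NA, rep("p1", n_children)),
                    c(NA, NA, rep("p2", n_children)),
                    c(1, 2, rep(c(1, 2), length.out = n_children))))
  }
  kid <- sprintf("g%d", seq_len(n_children))
  pedigree("fam1",
           c("gf", "gm", "p1", "sp", kid),
           c(NA, NA, "gf", NA, rep("p1", n_children)),
           c(NA, NA, "gm", NA, rep("sp", n_children)),
           c(1, 2, 1, 2, rep(c(1, 2), length.out = n_children)))
}

#' Configuration for pedigree gene-dropping
#'
#' Defaults follow the published linkage model: fully penetrant autosomal
#' dominant, no phenocopies, disease allele frequency 1e-4. Because a disease
#' allele at frequency 1e-4 essentially never segregates in an unascertained
#' family, the simulator mirrors ascertainment by forcing the first founder to
#' be a heterozygous carrier (disable with `force_carrier_founder = FALSE`).
#'
#' @param template A [pedigree] giving the topology, or a
#'   [pedigree_template()] name.
#' @param n_children Passed to [pedigree_template()] when `template` is a name.
#' @param disease_allele_freq,penetrance,phenocopy_rate Model parameters;
#'   `phenocopy_rate` overwrites `penetrance[1]`.
#' @param theta_true True recombination fraction between marker and disease
#'   locus, in `[0, 0.5]`.
#' @param marker_allele_freqs Marker allele frequencies (default four equally
#'   frequent alleles).
#' @param force_carrier_founder Force founder 1 heterozygous for the disease
#'   allele (default `TRUE`).
#' @param seed Integer seed.
#' @return An object of class `pedigree_sim_config`.
#' @export
pedigree_sim_config <- function(template = "nuclear", n_children = 4L,
                                disease_allele_freq = 1e-4,
                                penetrance = c(0, 1, 1), phenocopy_rate = 0,
                                theta_true = 0,
                                marker_allele_freqs = rep(0.25, 4),
                                force_carrier_founder = TRUE, seed = 1L) {
  if (is.character(template)) template <- pedigree_template(template, n_children)
  stopifnot(inherits(template, "pedigree"))
  if (has_pedigree_loop(template)) stop_input("unsupported structure: looped pedigree template")
  penetrance <- as.numeric(penetrance)
  penetrance[1] <- phenocopy_rate
  if (any(penetrance < 0 | penetrance > 1)) stop_input("penetrances must be in [0,1]")
  if (!(theta_true >= 0 && theta_true <= 0.5)) stop_input("`theta_true` must be in [0, 0.5]")
  structure(list(template = template, disease_allele_freq = disease_allele_freq,
                 penetrance = penetrance, theta_true = theta_true,
                 marker_allele_freqs = as.numeric(marker_allele_freqs),
                 force_carrier_founder = isTRUE(force_carrier_founder),
                 seed = as.integer(seed)),
            class = "pedigree_sim_config")
}

#' Gene-drop a pedigree with one linked marker
#'
#' Founder disease/marker haplotypes are drawn from the configured
#' frequencies; transmission is Mendelian with recombination `theta_true`
#' between the disease locus and the marker; affection is assigned by
#' penetrance. The returned pedigree carries the marker as `M1`; the truth
#' record stores each individual's disease-allele count and the phase.
#'
#' @param config A [pedigree_sim_config].
#' @return List with `ped` (a [pedigree]) and `truth`.
#' @export
simulate_pedigree <- function(config = pedigree_sim_config()) {
  stopifnot(inherits(config, "pedigree_sim_config"))
  with_seed(config$seed, {
    tpl <- config$template
    n <- tpl$n
    k <- length(config$marker_allele_freqs)
    fa <- match(tpl$father, tpl$id); mo <- match(tpl$mother, tpl$id)
    # haplotype per chromosome: column 1 = disease allele (1 = disease, 0 = wt),
    # column 2 = marker allele
    dis <- matrix(0L, n, 2); mar <- matrix(0L, n, 2)
    ord <- topo_order(fa, mo)
    first_founder <- ord[is.na(fa[ord])][1]
    for (i in ord) {
      if (is.na(fa[i])) {
        dis[i, ] <- stats::rbinom(2, 1, config$disease_allele_freq)
        if (config$force_carrier_founder && i == first_founder) dis[i, ] <- c(1L, 0L)
        mar[i, ] <- sample.int(k, 2, replace = TRUE, prob = config$marker_allele_freqs)
      } else {
        for (side in 1:2) {
          p <- if (side == 1) fa[i] else mo[i]
          strand <- sample.int(2, 1)
          dis[i, side] <- dis[p, strand]
          rec <- stats::runif(1) < config$theta_true
          mar[i, side] <- mar[p, if (rec) 3L - strand else strand]
        }
      }
    }
    ndis <- rowSums(dis)
    affected <- stats::runif(n) < config$penetrance[ndis + 1L]
    ped <- pedigree(tpl$family, tpl$id, tpl$father, tpl$mother, tpl$sex,
                    ifelse(affected, "affected", "unaffected"),
                    markers = list(M1 = mar))
    list(ped = ped,
         truth = list(theta_true = config$theta_true, disease_copies = ndis,
                      phase = list(disease = dis, marker = mar)))
  })
}

topo_order <- function(fa, mo) {
  n <- length(fa)
  ord <- integer(0); placed <- rep(FALSE, n)
  while (length(ord) < n) {
    ready <- which(!placed & vapply(seq_len(n), function(i) {
      (is.na(fa[i]) || placed[fa[i]]) && (is.na(mo[i]) || placed[mo[i]])
    }, logical(1)))
    ord <- c(ord, ready); placed[ready] <- TRUE
  }
  ord
}

#' Simulate carrier families sharing k founder haplotypes
#'
#' Draws `k_founders` distinct marker haplotypes and builds `n_families`
#' genotyped trios (carrier parent, non-carrier parent, carrier child). Each
#' family's variant-bearing chromosome copies one of the founder haplotypes
#' (families cycle through the founders, so every founder is represented);
#' all other chromosomes are drawn from the population allele frequencies. No
#' recombination is modelled inside the small marker window.
#'
#' @param k_founders Number of independent founder chromosomes (>= 1).
#' @param n_families Number of carrier families (`k_founders <= n_families`).
#' @param markers A [marker_panel]; default five 8-allele STRs and four SNPs,
#'   echoing a typical microsatellite fine-mapping panel.
#' @param seed Integer seed.
#' @return List with `families` (each: `ped`, `carrier_status`,
#'   `founder_index`) and `truth` (`k_founders`, matrix of founder
#'   haplotypes).
#' @export
simulate_founder_haplotypes <- function(k_founders, n_families,
                                        markers = default_marker_panel(),
                                        seed = 1L) {
  if (!is_count(k_founders) || k_founders < 1) stop_input("`k_founders` must be >= 1")
  if (k_founders > n_families) stop_input("need k_founders <= n_families")
  k_founders <- as.integer(k_founders); n_families <- as.integer(n_families)
  stopifnot(inherits(markers, "marker_panel"))
  with_seed(seed, {
    draw_hap <- function() {
      vapply(markers$freqs, function(f) sample.int(length(f), 1, prob = f), integer(1))
    }
    founders <- matrix(NA_integer_, k_founders, markers$n,
                       dimnames = list(NULL, markers$name))
    for (tries in seq_len(1000)) {
      for (j in seq_len(k_founders)) founders[j, ] <- draw_hap()
      if (!anyDuplicated(founders)) break
      if (tries == 1000) stop_input("could not draw %d distinct haplotypes", k_founders)
    }
    fams <- lapply(seq_len(n_families), function(i) {
      fidx <- (i - 1L) %% k_founders + 1L
      hap_c <- founders[fidx, ]
      father <- rbind(hap_c, draw_hap())          # carrier chromosome first
      mother <- rbind(draw_hap(), draw_hap())
      child <- rbind(hap_c, mother[sample.int(2, 1), ])
      gmat <- lapply(seq_len(markers$n), function(m) {
        rbind(father[, m], mother[, m], child[, m])
      })
      names(gmat) <- markers$name
      ped <- pedigree(sprintf("fam%03d", i), c("fa", "mo", "ch"),
                      c(NA, NA, "fa"), c(NA, NA, "mo"), c(1, 2, 1),
                      c("affected", "unaffected", "affected"), gmat)
      list(ped = ped, carrier_status = c(TRUE, FALSE, TRUE),
           founder_index = fidx)
    })
    list(families = fams,
         truth = list(k_founders = k_founders, haplotypes = founders))
  })
}

#' Default STR/SNP fine-mapping panel used by the founder simulator
#' @return A [marker_panel] with five 8-allele STRs and four SNPs.
#' @export
default_marker_panel <- function() {
  marker_panel(
    name = c("STR1", "STR2", "SNP1", "SNP2", "STR3", "SNP3", "STR4", "SNP4", "STR5"),
    type = c("STR", "STR", "SNP", "SNP", "STR", "SNP", "STR", "SNP", "STR"),
    position = c(88100000, 88300000, 88500000, 88560000, 88569000,
                 88580000, 88700000, 88900000, 89100000),
    freqs = list(rep(1 / 8, 8), rep(1 / 8, 8), c(0.6, 0.4), c(0.7, 0.3),
                 rep(1 / 8, 8), c(0.5, 0.5), rep(1 / 8, 8), c(0.8, 0.2),
                 rep(1 / 8, 8))
  )
}

#' Simulate per-cell-type coverage tracks with one selective peak
#'
#' All cell types share an i.i.d. baseline; the target cell type gets
#' `peak_height` added over `peak_region`. With `noise = "none"` the tracks
#' are exactly `baseline` outside the peak, which makes the selectivity score
#' at the peak a closed-form quantity.
#'
#' @param n_cell_types Number of tracks (default 154, the size of the public
#'   single-nucleus atlas the score was defined over).
#' @param interval Declared [genomic_interval] of all tracks (default a 2-kb
#'   window around the microsatellite).
#' @param peak_region A [genomic_interval] inside `interval`.
#' @param target_cell_type Name given to the selective track (default
#'   `"thyroid_follicular"`); remaining tracks are `CT002...`.
#' @param peak_height Added depth over the peak (default 10).
#' @param baseline Baseline depth (default 1).
#' @param noise `"lognormal"` (multiplicative, `sdlog`) or `"none"`.
#' @param sdlog Lognormal sigma (default 0.3).
#' @param bin_width Bin width in bases (default 100).
#' @param seed Integer seed.
#' @return List of [coverage_track]s.
#' @export
simulate_coverage_tracks <- function(n_cell_types = 154L,
                                     interval = genomic_interval("chr15", 88568001, 88570000),
                                     peak_region = genomic_interval("chr15", 88569201, 88569700),
                                     target_cell_type = "thyroid_follicular",
                                     peak_height = 10, baseline = 1,
                                     noise = c("lognormal", "none"), sdlog = 0.3,
                                     bin_width = 100L, seed = 1L) {
  noise <- match.arg(noise)
  if (!is_count(n_cell_types) || n_cell_types < 2) stop_input("need >= 2 cell types")
  if (!intervals_overlap(interval, peak_region) ||
      peak_region$start < interval$start || peak_region$end > interval$end) {
    stop_input("peak region must lie within the declared interval")
  }
  if (peak_height < 0 || baseline < 0) stop_input("peak_height and baseline must be >= 0")
  nb <- ceiling(interval_length(interval) / bin_width)
  cts <- c(target_cell_type, sprintf("CT%03d", seq_len(n_cell_types)[-1]))
  b1 <- (peak_region$start - interval$start) %/% bin_width + 1
  b2 <- (peak_region$end - interval$start) %/% bin_width + 1
  with_seed(seed, {
    lapply(cts, function(ct) {
      depths <- rep(baseline, nb)
      if (noise == "lognormal") {
        depths <- depths * stats::rlnorm(nb, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      if (ct == target_cell_type) depths[b1:b2] <- depths[b1:b2] + peak_height
      coverage_track(ct, interval, bin_width, depths)
    })
  })
}

#' Synthetic reference around the TTTG microsatellite
#'
#' Random non-repetitive flanks around a perfect `(TTTG)`-unit tract placed at
#' the printed locus coordinates (tract start chr15:88,569,434 for the
#' 4-copy reference). Flanks are redrawn until the maximal perfect run at the
#' anchor has exactly `n_units` copies and the tract sits at the annotated
#' coordinates, so no flank base extends the repeat. The true flanking
#' sequence is not embedded; this synthetic stand-in preserves only the
#' printed coordinates.
#'
#' @param flank_length Flank length on each side (>= 20; default 200).
#' @param n_units Tract copy number (default 4; 3 emulates the disease allele,
#'   5 the registered expansion).
#' @param seed Integer seed.
#' @param chrom,tract_start,unit Locus anchoring (defaults chr15, 88,569,434,
#'   `"TTTG"`).
#' @return A [ref_seq] with attribute `locus` (a [repeat_locus] whose
#'   `ref_units = n_units`).
#' @export
make_repeat_locus_reference <- function(flank_length = 200L, n_units = 4L,
                                        seed = 1L, chrom = "chr15",
                                        tract_start = 88569434, unit = "TTTG") {
  if (!is_count(flank_length) || flank_length < 20) stop_input("`flank_length` must be >= 20")
  if (!is_count(n_units) || n_units < 1) stop_input("`n_units` must be >= 1")
  ulen <- nchar(unit)
  tract <- genomic_interval(chrom, tract_start, tract_start + n_units * ulen - 1)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    for (tries in seq_len(1000)) {
      left <- paste(sample(bases, flank_length, replace = TRUE), collapse = "")
      right <- paste(sample(bases, flank_length, replace = TRUE), collapse = "")
      seqs <- paste0(left, strrep(unit, n_units), right)
      ref <- ref_seq(chrom, tract_start - flank_length, seqs)
      found <- find_repeat_tract(ref, unit, tract_start)
      if (found$unit_count == n_units &&
          found$tract$start == tract$start && found$tract$end == tract$end) {
        locus <- repeat_locus(chrom, tract, unit, n_units)
        return(structure(ref, locus = locus))
      }
    }
    stop_input("failed to draw non-extending flanks")  # practically unreachable
  })
}

#' Packaged luciferase reporter fixture (synthetic)
#'
#' A synthetic hexaplicate table emulating a repressor-activity readout:
#' control (promoter-only) activities with mean 1.0 and repressor-construct
#' activities with mean 0.68 — a 32% reduction with ~6% spread. Demo input for
#' [welch_t_test()]; the values are fixture inputs, not measurements.
#'
#' @return data.frame with columns `group`, `activity`.
#' @export
luciferase_fixture <- function() {
  path <- system.file("extdata", "luciferase_synthetic.tsv", package = "chng3",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
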