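#' Run the end-to-end discovery-chain demo on synthetic data
#'
#' Reproduces the pipeline's stages on seeded synthetic inputs: (1) simulate a
#' case/control cohort with one spiked 500-bp window and run the rare-variant
#' density scan; (2) genotype the microsatellite deletion on a synthetic
#' reference; (3) simulate carrier families, phase their haplotypes and count
#' founder chromosomes; (4) compute the headline cohort enrichment and
#' prevalence statistics from the published count tables; (5) score cell-type
#' selectivity on simulated coverage tracks. Writes per-stage TSVs and a JSON
#' manifest recording parameters and seeds.
#'
#' @param seed Integer master seed (sub-stage seeds are fixed offsets of it).
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with each stage's result and the manifest.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("chng3_demo_"), verbose = TRUE) {
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    chng3_log("[%s] running", name, verbose = verbose)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  scan <- stage("scan", {
    sim <- simulate_cohort(cohort_sim_config(seed = seed))
    res <- run_scan(sim$cohort, sim$panel, scan_config())
    write_scan_tsv(res, file.path(out_dir, "scan.tsv"))
    top <- res$bins[res$bins$rank == 1L, ]
    list(result = res, truth = sim$truth,
         top_bin_index = which(res$bins$rank == 1L),
         top_is_truth = which(res$bins$rank == 1L) == sim$truth$spiked_bin_index,
         n_significant = sum(res$bins$significant), top = top)
  })

  repeat_calls <- stage("genotype-repeat", {
    ref <- make_repeat_locus_reference(seed = seed + 1L)
    locus <- attr(ref, "locus")
    anchor <- locus$tract$start - 1
    del <- variant_record(locus$chrom, anchor, ref_base_at(ref, anchor, 5),
                          ref_base_at(ref, anchor, 1))
    snv_pos <- locus$tract$start + 14  # homologous to the printed repeat-internal SNV
    snv <- variant_record(locus$chrom, snv_pos, ref_base_at(ref, snv_pos), "C")
    het <- genotype_sample(locus, ref, list(del), 1L)
    hom <- genotype_sample(locus, ref, list(del), 2L)
    snv_call <- call_repeat_allele(locus, ref, snv)
    df <- data.frame(
      sample = c("het_del", "hom_del", "snv"),
      allele1 = c(het[[1]]$allele_class, hom[[1]]$allele_class, "REF"),
      allele2 = c(het[[2]]$allele_class, hom[[2]]$allele_class, snv_call$allele_class),
      unit_count = c(het[[2]]$unit_count, hom[[2]]$unit_count, snv_call$unit_count))
    utils::write.table(df, file.path(out_dir, "repeat_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(het = het, hom = hom, snv = snv_call, table = df)
  })

  haplotypes <- stage("haplotypes", {
    sim <- simulate_founder_haplotypes(k_founders = 4, n_families = 12,
                                       seed = seed + 2L)
    haps <- lapply(sim$families, function(f) {
      phase_carriers(f$ped, f$carrier_status)
    })
    cnt <- count_founder_haplotypes(haps)
    df <- data.frame(
      family = vapply(haps, function(h) h$family, character(1)),
      haplotype = vapply(haps, function(h) {
        paste(ifelse(is.na(h$alleles), ".", h$alleles), collapse = "-")
      }, character(1)),
      completeness = vapply(haps, function(h) h$completeness, numeric(1)),
      group = as.integer(cnt$groups))
    utils::write.table(df, file.path(out_dir, "haplotypes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(count = cnt, truth = sim$truth, table = df)
  })

  stats_out <- stage("stats", {
    mng <- fisher_exact_one_sided(3, 30, 3, 38719)
    yield <- diagnostic_yield(data.frame(
      subgroup = c("whole_cohort", "family_history", "parent_to_offspring"),
      carriers = c(137, 117, 57), n = c(989, 282, 76)))
    prev <- prevalence_estimate(3, 38722)
    luc <- luciferase_fixture()
    welch <- welch_t_test(luc$activity[luc$group == "control"],
                          luc$activity[luc$group == "repressor"])
    utils::write.table(yield, file.path(out_dir, "diagnostic_yield.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(mng_fisher = mng, yield = yield, prevalence = prev, welch = welch)
  })

  selectivity <- stage("selectivity", {
    tracks <- simulate_coverage_tracks(seed = seed + 3L)
    peak <- genomic_interval("chr15", 88569201, 88569700)
    sel <- selectivity_score(tracks, peak, "thyroid_follicular")
    df <- data.frame(cell_type = names(sel$selectivity),
                     median_depth = as.numeric(sel$medians),
                     selectivity = as.numeric(sel$selectivity))
    utils::write.table(df[order(-df$selectivity), ],
                       file.path(out_dir, "selectivity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sel
  })

  manifest <- list(
    package = "chng3",
    version = as.character(utils::packageVersion("chng3")),
    seed = seed,
    stage_seeds = list(scan = seed, repeat_reference = seed + 1L,
                       haplotypes = seed + 2L, coverage = seed + 3L),
    parameters = list(
      scan = list(region = format_interval(scan_config()$region), bin_width = 500,
                  rare_threshold = 0.002, alpha = 0.05),
      cohort = list(n_cases = 25, n_controls = 56, background_rare_rate = 0.0094,
                    spike_carrier_fraction_cases = 0.7),
      haplotypes = list(k_founders = 4, n_families = 12),
      selectivity = list(n_cell_types = 154, bin_width = 100)),
    results = list(top_bin_is_truth = scan$top_is_truth,
                   n_significant_bins = scan$n_significant,
                   founder_haplotypes = haplotypes$count$k,
                   target_selectivity = selectivity$target_selectivity))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  chng3_log("demo complete: %s", out_dir, verbose = verbose)
  invisible(list(scan = scan, repeat_calls = repeat_calls,
                 haplotypes = haplotypes, stats = stats_out,
                 selectivity = selectivity, manifest = manifest,
                 out_dir = out_dir))
}
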