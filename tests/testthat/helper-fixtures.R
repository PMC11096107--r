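# Shared fixture builders; everything is generated in code at test time.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

vcf_lines <- function(rows, samples = c("s1", "s2")) {
  c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows)
}

# tiny hand-built cohort: 3 variants x 4 samples (2 cases, 2 controls)
tiny_cohort <- function() {
  cohort_variants(
    variants = data.frame(chrom = "chr15", pos = c(86206100, 86206200, 86206900),
                          id = ".", ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                          stringsAsFactors = FALSE),
    samples = c("ca1", "ca2", "co1", "co2"),
    group = c("case", "case", "control", "control"),
    genotypes = rbind(c(1L, 0L, 0L, 0L),
                      c(1L, 1L, 0L, NA),
                      c(0L, 2L, 1L, 0L)))
}

# random small pedigree + simulated marker data for likelihood property tests
random_linkage_case <- function(seed) {
  set.seed(seed)
  tpl <- sample(c("trio", "nuclear", "threegen"), 1)
  nch <- sample(2:4, 1)
  k <- sample(2:4, 1)
  theta_true <- sample(c(0, 0.1, 0.3, 0.5), 1)
  cfg <- pedigree_sim_config(template = tpl, n_children = nch,
                             theta_true = theta_true,
                             marker_allele_freqs = rep(1 / k, k),
                             seed = seed)
  list(ped = simulate_pedigree(cfg)$ped, marker = marker_data(rep(1 / k, k)),
       theta = sample(c(0, 0.05, 0.2, 0.35, 0.5), 1))
}

# three-generation phase-known fixture: grandfather 1/1 affected, grandmother
# 3/3 unaffected, carrier child 1/3, married-in spouse 4/4, n affected
# grandchildren all 1/4 (non-recombinant meioses)
phase_known_fixture <- function(n_meioses) {
  tpl <- pedigree_template("threegen", n_children = n_meioses)
  mar <- rbind(c(1, 1), c(3, 3), c(1, 3), c(4, 4),
               matrix(rep(c(1, 4), n_meioses), ncol = 2, byrow = TRUE))
  pedigree(tpl$family, tpl$id, tpl$father, tpl$mother, tpl$sex,
           c("affected", "unaffected", "affected", "unaffected",
             rep("affected", n_meioses)),
           markers = list(M1 = mar))
}
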