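test_that("make_bins partitions regions exactly, truncating the last bin", {
  paper_region <- genomic_interval("chr15", 86206001, 89412500)
  bins <- make_bins(paper_region, 500)
  expect_length(bins, 6413L)
  expect_true(all(vapply(bins, interval_length, numeric(1)) == 500))

  b2 <- make_bins(genomic_interval("chr1", 1, 1000), 500)
  expect_length(b2, 2L)
  b3 <- make_bins(genomic_interval("chr1", 1, 1001), 500)
  expect_length(b3, 3L)
  expect_equal(interval_length(b3[[3]]), 1)
  # bin_width larger than the region: a single truncated bin, not an error
  b1 <- make_bins(genomic_interval("chr1", 10, 20), 500)
  expect_length(b1, 1L)
  expect_equal(interval_length(b1[[1]]), 11)
})

test_that("bins are disjoint and their union is the region (random cases)", {
  set.seed(42)
  for (rep in 1:25) {
    start <- sample.int(1e6, 1)
    len <- sample.int(5000, 1)
    width <- sample.int(700, 1)
    region <- genomic_interval("chrX", start, start + len - 1)
    bins <- make_bins(region, width)
    starts <- vapply(bins, function(b) b$start, numeric(1))
    ends <- vapply(bins, function(b) b$end, numeric(1))
    expect_equal(starts[1], region$start)
    expect_equal(ends[length(ends)], region$end)
    if (length(bins) > 1) expect_equal(starts[-1], ends[-length(ends)] + 1)
    expect_equal(sum(ends - starts + 1), interval_length(region))
  }
})

test_that("rarity classification uses a strict panel-frequency cutoff", {
  cohort <- tiny_cohort()
  keys <- rownames(cohort$genotypes)
  panel <- panel_frequencies(keys[1:2], c(0.0019, 0.002))
  rare <- classify_rare(cohort, panel, 0.002)
  expect_true(keys[1] %in% rare)    # 0.0019 < 0.002
  expect_false(keys[2] %in% rare)   # 0.002 is not rare (strict inequality)
  expect_true(keys[3] %in% rare)    # absent from panel -> AF 0 -> rare
})

test_that("carrier counting is per-individual and missing genotypes never count", {
  cohort <- tiny_cohort()  # variants at pos 86206100/86206200 share bin 1
  cfg <- scan_config(region = genomic_interval("chr15", 86206001, 86207000),
                     bin_width = 500)
  rare <- rownames(cohort$genotypes)  # all rare
  tab <- count_bin_carriers(cohort, rare, cfg)
  # ca1 has two rare variants in bin 1 but is one carrier; ca2 has one;
  # co2 genotype is missing at the bin-1 variant -> not a carrier,
  # denominator unchanged
  expect_equal(tab$a[1], 2L)
  expect_equal(tab$b[1], 0L)
  expect_equal(tab$c[1], 0L)
  expect_equal(tab$d[1], 2L)
  # bin 2 has one variant (hom in ca2, het in co1)
  expect_equal(tab$a[2], 1L)
  expect_equal(tab$c[2], 1L)
})

test_that("a bin with no rare variants yields the empty 2x2 table", {
  cohort <- tiny_cohort()
  cfg <- scan_config(region = genomic_interval("chr15", 86206001, 86208000),
                     bin_width = 500)
  tab <- count_bin_carriers(cohort, character(0), cfg)
  expect_true(all(tab$a == 0 & tab$c == 0))
  expect_true(all(tab$b == 2 & tab$d == 2))
})

test_that("a shared deletion carried by 8 of 11 case families gives a = 8", {
  # one sequenced patient per family, mirroring the screen's unsolved families
  n_fam <- 11; n_ctrl <- 20
  pos <- 86206251
  variants <- data.frame(chrom = "chr15", pos = pos, id = "del",
                         ref = "CTTTG", alt = "C", stringsAsFactors = FALSE)
  geno <- matrix(c(rep(1L, 8), rep(0L, 3), rep(0L, n_ctrl)), nrow = 1)
  cohort <- cohort_variants(variants,
                            c(sprintf("fam%02d", 1:n_fam), sprintf("ct%02d", 1:n_ctrl)),
                            rep(c("case", "control"), c(n_fam, n_ctrl)), geno)
  cfg <- scan_config(region = genomic_interval("chr15", 86206001, 86211000),
                     bin_width = 500)
  tab <- count_bin_carriers(cohort, rownames(cohort$genotypes), cfg)
  expect_equal(tab$a[1], 8L)
  expect_equal(tab$c[1], 0L)
})

test_that("run_scan applies the Bonferroni threshold and ranks by p then position", {
  res <- run_scan(tiny_cohort(), panel_frequencies(character(0), numeric(0)),
                  scan_config(region = genomic_interval("chr15", 86206001, 86208000),
                              bin_width = 500))
  expect_equal(res$threshold, 0.05 / res$n_bins)
  expect_equal(sort(res$bins$rank), seq_len(res$n_bins))
  # equal-p bins are ranked by genomic position
  tied <- res$bins[res$bins$p == 1, ]
  expect_true(all(diff(tied$bin_start[order(tied$rank)]) > 0))
})

test_that("identical case/control carrier patterns are never significant", {
  variants <- data.frame(chrom = "chr15", pos = c(86206100, 86206600), id = ".",
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  geno <- rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L))
  cohort <- cohort_variants(variants, c("a", "b", "c", "d"),
                            c("case", "case", "control", "control"), geno)
  res <- run_scan(cohort, panel_frequencies(character(0), numeric(0)),
                  scan_config(region = genomic_interval("chr15", 86206001, 86207000),
                              bin_width = 500))
  expect_equal(sum(res$bins$significant), 0L)
  expect_true(all(res$bins$p >= 0.5))
})

test_that("scan requires both groups and p is invariant to within-group relabeling", {
  cohort <- tiny_cohort()
  all_case <- cohort_variants(cohort$variants, cohort$samples,
                              rep("case", 4), cohort$genotypes)
  expect_error(run_scan(all_case, panel_frequencies(character(0), numeric(0))),
               "case and one control")
  cfg <- scan_config(region = genomic_interval("chr15", 86206001, 86208000),
                     bin_width = 500)
  panel <- panel_frequencies(character(0), numeric(0))
  res1 <- run_scan(cohort, panel, cfg)
  perm <- cohort_variants(cohort$variants, cohort$samples[c(2, 1, 4, 3)],
                          unname(cohort$group[c(2, 1, 4, 3)]),
                          cohort$genotypes[, c(2, 1, 4, 3)])
  res2 <- run_scan(perm, panel, cfg)
  expect_equal(res1$bins$p, res2$bins$p)
})

test_that("allele-count mode uses chromosome denominators", {
  cohort <- tiny_cohort()
  cfg <- scan_config(region = genomic_interval("chr15", 86206001, 86208000),
                     bin_width = 500, unit = "alleles")
  tab <- count_bin_carriers(cohort, rownames(cohort$genotypes), cfg)
  expect_equal(tab$a[1] + tab$b[1], 2L * 2L)  # 2 cases x 2 chromosomes
  expect_equal(tab$a[2], 2L)                   # hom carrier counts 2 alleles
})

test_that("variants outside the scan region are ignored but reported", {
  cohort <- tiny_cohort()
  cfg <- scan_config(region = genomic_interval("chr15", 86206001, 86206500),
                     bin_width = 500)
  res <- run_scan(cohort, panel_frequencies(character(0), numeric(0)), cfg)
  expect_equal(res$n_outside_region, 1L)  # pos 86206900 falls outside
})
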