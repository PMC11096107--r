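test_that("VCF round-trip write/read is the identity on cohort tables", {
  sim <- simulate_cohort(cohort_sim_config(
    region = genomic_interval("chr15", 86206001, 86306000),
    spiked_bin_index = 50L, seed = 11))
  path <- tempfile(fileext = ".vcf")
  write_vcf_lite(sim$cohort, path)
  back <- read_vcf_lite(path, group = unname(sim$cohort$group))
  expect_equal(back$variants, sim$cohort$variants, ignore_attr = TRUE)
  expect_identical(back$samples, sim$cohort$samples)
  expect_equal(unname(back$genotypes), unname(sim$cohort$genotypes))
  expect_identical(unname(back$group), unname(sim$cohort$group))
})

test_that("multi-allelic rows split and diploid GT parses to allele counts", {
  path <- write_tmp(vcf_lines(c(
    "chr15\t100\t.\tC\tA,T\t.\tPASS\t.\tGT\t1/2\t0/0",
    "chr15\t200\t.\tG\tA\t.\tPASS\t.\tGT\t1/1\t./.")), ext = ".vcf")
  x <- read_vcf_lite(path)
  expect_equal(nrow(x$variants), 3L)
  expect_equal(x$variants$pos[1:2], c(100, 100))
  expect_equal(x$variants$ref[1:2], c("C", "C"))
  expect_equal(x$variants$alt[1:2], c("A", "T"))
  expect_equal(unname(x$genotypes[1, ]), c(1L, 0L))  # one copy of ALT1 in 1/2
  expect_equal(unname(x$genotypes[2, ]), c(1L, 0L))
  expect_equal(unname(x$genotypes[3, ]), c(2L, NA))  # 1/1 -> 2; ./. -> missing
})

test_that("malformed VCF input errors name the offending line", {
  bad_gt <- write_tmp(vcf_lines("chr15\t100\t.\tC\tA\t.\tPASS\t.\tGT\tx/y\t0/0"),
                      ext = ".vcf")
  expect_error(read_vcf_lite(bad_gt), "line 3")
  dup <- write_tmp(vcf_lines(character(0), samples = c("s1", "s1")), ext = ".vcf")
  expect_error(read_vcf_lite(dup), "duplicate sample")
})

test_that("PED parsing resolves parents, founders and affection codes", {
  path <- write_tmp(c("fam1 p1 0 0 1 2 1 2",
                      "fam1 p2 0 0 2 1 3 3",
                      "fam1 c1 p1 p2 1 0 1 3"))
  ped <- read_ped(path)
  expect_equal(sum(!is_founder(ped)), 1L)
  expect_equal(ped$affection, c("affected", "unaffected", "unknown"))
  expect_equal(ped$markers$M1[3, ], c(1L, 3L))
  # round trip
  out <- tempfile(fileext = ".ped")
  write_ped(ped, out)
  back <- read_ped(out)
  expect_equal(back[c("family", "id", "father", "mother", "sex", "affection")],
               ped[c("family", "id", "father", "mother", "sex", "affection")])
  expect_equal(back$markers, ped$markers)
})

test_that("PED structural errors are caught", {
  missing_parent <- write_tmp(c("f1 p2 0 0 2 1", "f1 c1 p1 p2 1 2"))
  expect_error(read_ped(missing_parent), "link error")
  cycle <- write_tmp(c("f1 a b c 1 1", "f1 b a c 1 1", "f1 c 0 0 2 1"))
  expect_error(read_ped(cycle), "cycle")
  one_parent <- write_tmp("f1 c1 p1 0 1 2")
  expect_error(read_ped(one_parent), "both or none")
})

test_that("bedGraph resampling onto fixed bins follows the coverage-weighted rule", {
  iv <- genomic_interval("chr15", 1, 300)
  # single record covering exactly bin 1
  t1 <- read_bedgraph(write_tmp("chr15\t0\t100\t5.0"), 100, interval = iv)
  expect_equal(t1$depths, c(5, 0, 0))
  # record spanning two bins equally: both bins get the value
  t2 <- read_bedgraph(write_tmp("chr15\t50\t150\t4.0"), 100, interval = iv)
  expect_equal(t2$depths[1:2], c(4, 4))
  # empty file -> zero track
  t3 <- read_bedgraph(write_tmp(character(0)), 100, interval = iv)
  expect_equal(t3$depths, c(0, 0, 0))
})

test_that("bedGraph validation rejects overlaps and negative values", {
  expect_error(read_bedgraph(write_tmp(c("chr15\t0\t100\t1", "chr15\t50\t150\t1")), 100),
               "overlapping")
  expect_error(read_bedgraph(write_tmp("chr15\t0\t100\t-1"), 100), "negative")
})

test_that("bedGraph round-trip preserves a coverage track", {
  tracks <- simulate_coverage_tracks(n_cell_types = 2, seed = 5)
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tracks[[1]], path)
  back <- read_bedgraph(path, bin_width = tracks[[1]]$bin_width,
                        interval = tracks[[1]]$interval,
                        cell_type = tracks[[1]]$cell_type)
  expect_equal(back$depths, tracks[[1]]$depths, tolerance = 1e-12)
})

test_that("0-based half-open bedGraph coordinates reconcile with 1-based bins", {
  # bedGraph (s-1, e) covers the same bases as 1-based s..e
  iv <- genomic_interval("chr1", 11, 110)
  tr <- read_bedgraph(write_tmp("chr1\t10\t110\t3"), 100, interval = iv)
  expect_equal(tr$depths, 3)
})

test_that("FASTA round-trip preserves the anchored reference", {
  ref <- make_repeat_locus_reference(flank_length = 30, seed = 9)
  path <- tempfile(fileext = ".fa")
  write_fasta_ref(ref, path)
  back <- read_fasta_ref(path)
  expect_equal(back$seq, ref$seq)
  expect_equal(back$start, ref$start)
  expect_equal(back$chrom, ref$chrom)
})

test_that("genomic intervals enforce 1-based inclusive invariants", {
  expect_equal(interval_length(genomic_interval("chr15", 86206051, 89412131)),
               3206081)
  expect_error(genomic_interval("chr1", 0, 10), "start")
  expect_error(genomic_interval("chr1", 10, 5), "end")
  expect_equal(parse_region("chr15:86,206,001-89,412,500")$end, 89412500)
})

test_that("VCF genotype parsing agrees with vcfR on a round-tripped file", {
  skip_if_not_installed("vcfR")
  sim <- simulate_cohort(cohort_sim_config(
    region = genomic_interval("chr15", 86206001, 86256000),
    spiked_bin_index = 10L, seed = 13))
  path <- tempfile(fileext = ".vcf")
  write_vcf_lite(sim$cohort, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt))
  counts[gt == "0/0"] <- 0L; counts[gt == "0/1"] <- 1L; counts[gt == "1/1"] <- 2L
  expect_equal(unname(counts), unname(sim$cohort$genotypes))
  expect_equal(as.numeric(vcfR::getPOS(v)), sim$cohort$variants$pos)
})

test_that("FASTA output is readable by Biostrings with identical sequence", {
  skip_if_not_installed("Biostrings")
  ref <- make_repeat_locus_reference(flank_length = 40, seed = 15)
  path <- tempfile(fileext = ".fa")
  write_fasta_ref(ref, path)
  ss <- Biostrings::readDNAStringSet(path)
  expect_equal(unname(as.character(ss[[1]])), ref$seq)
})
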