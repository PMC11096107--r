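# fixed synthetic reference carrying (TTTG)4 at the printed coordinates
ref4 <- make_repeat_locus_reference(flank_length = 60, n_units = 4, seed = 17)
locus4 <- attr(ref4, "locus")
TSTART <- locus4$tract$start  # 88,569,434

test_that("every equivalent placement of the 4-bp deletion normalizes identically", {
  # deleting any aligned TTTG unit (or any 4-mer window inside the tract that
  # leaves a 3-unit tract) is the same allele
  norm <- list()
  for (offset in 0:12) {
    pos <- TSTART + offset - 1          # anchor base before the deleted 4-mer
    v <- variant_record("chr15", pos, ref_base_at(ref4, pos, 5),
                        ref_base_at(ref4, pos, 1))
    n <- normalize_variant(ref4, v)
    norm[[length(norm) + 1L]] <- variant_key(n)
  }
  expect_length(unique(unlist(norm)), 1L)
})

test_that("SNVs and minimal records pass through normalization unchanged", {
  pos <- TSTART + 14
  v <- variant_record("chr15", pos, ref_base_at(ref4, pos), "C")
  expect_equal(variant_key(normalize_variant(ref4, v)), variant_key(v))
  bad <- variant_record("chr15", pos, "A", "C")
  if (ref_base_at(ref4, pos) != "A") expect_error(normalize_variant(ref4, bad),
                                                  "REF mismatch")
})

test_that("homopolymer-adjacent representations collapse to one key", {
  # 30-bp fixture with a T homopolymer: TTTTG where one T is deleted can be
  # written as TTTTG>TTTG at several offsets
  fx <- ref_seq("chrT", 101, "ACGACGACGTTTTTGACGACGACGACGACG")
  keys <- character(0)
  for (pos in 110:113) {  # anchor bases before each deletable T
    v <- variant_record("chrT", pos, ref_base_at(fx, pos, 2), ref_base_at(fx, pos, 1))
    keys <- c(keys, variant_key(normalize_variant(fx, v)))
  }
  expect_length(unique(keys), 1L)
})

test_that("find_repeat_tract counts maximal perfect runs at the anchor", {
  s <- "ACTTTGTTTGTTTGTTTGCA"
  expect_equal(find_repeat_tract(s, "TTTG", 5)$unit_count, 4L)
  # one internal unit mutated to TTCG: the maximal perfect run has 3 copies
  s2 <- "ACTTTGTTCGTTTGTTTGTTTGCA"
  hit <- find_repeat_tract(s2, "TTTG", 12)
  expect_equal(hit$unit_count, 3L)
  expect_equal(find_repeat_tract("ACGTACGTACGT", "TTTG", 3)$unit_count, 0L)
})

test_that("the printed 4-bp deletion calls UNIT_LOSS with three copies", {
  pos <- TSTART - 1
  del <- variant_record("chr15", pos, ref_base_at(ref4, pos, 5),
                        ref_base_at(ref4, pos, 1))
  call <- call_repeat_allele(locus4, ref4, del)
  expect_equal(call$allele_class, "UNIT_LOSS")
  expect_equal(call$unit_count, 3L)
})

test_that("repeat calling is invariant over all equivalent deletion placements", {
  for (offset in 0:12) {
    pos <- TSTART + offset - 1
    del <- variant_record("chr15", pos, ref_base_at(ref4, pos, 5),
                          ref_base_at(ref4, pos, 1))
    call <- call_repeat_allele(locus4, ref4, del)
    expect_equal(call$allele_class, "UNIT_LOSS", label = sprintf("offset %d", offset))
    expect_equal(call$unit_count, 3L)
  }
})

test_that("the repeat-internal substitution calls SNV_DISRUPTED", {
  pos <- TSTART + 14  # homologous to the printed chr15:88,569,448 T>C
  expect_equal(pos, 88569448)
  snv <- variant_record("chr15", pos, ref_base_at(ref4, pos), "C")
  call <- call_repeat_allele(locus4, ref4, snv)
  expect_equal(call$allele_class, "SNV_DISRUPTED")
  expect_lt(call$unit_count, 4L)
  expect_equal(call$disrupting_change$pos, pos)
})

test_that("a one-unit insertion calls UNIT_GAIN with five copies", {
  pos <- TSTART - 1
  ins <- variant_record("chr15", pos, ref_base_at(ref4, pos, 1),
                        paste0(ref_base_at(ref4, pos, 1), "TTTG"))
  call <- call_repeat_allele(locus4, ref4, ins)
  expect_equal(call$allele_class, "UNIT_GAIN")
  expect_equal(call$unit_count, 5L)
})

test_that("variants beyond the flank window are OUT_OF_SCOPE, not errors", {
  far_ref <- make_repeat_locus_reference(flank_length = 200, seed = 3)
  far_locus <- attr(far_ref, "locus")
  pos <- far_locus$tract$start - 150  # outside the 100-bp flank window
  v <- variant_record("chr15", pos, ref_base_at(far_ref, pos),
                      setdiff(c("A", "C", "G", "T"), ref_base_at(far_ref, pos))[1])
  expect_equal(call_repeat_allele(far_locus, far_ref, v)$allele_class, "OUT_OF_SCOPE")
})

test_that("non-repeat in-scope changes classify as OTHER", {
  pos <- TSTART - 10  # in the flank, inside the window
  v <- variant_record("chr15", pos, ref_base_at(ref4, pos, 3), ref_base_at(ref4, pos, 1))
  expect_equal(call_repeat_allele(locus4, ref4, v)$allele_class, "OTHER")
})

test_that("sample diplotypes follow zygosity and ambiguity rules", {
  pos <- TSTART - 1
  del <- variant_record("chr15", pos, ref_base_at(ref4, pos, 5),
                        ref_base_at(ref4, pos, 1))
  snv <- variant_record("chr15", TSTART + 14, ref_base_at(ref4, TSTART + 14), "C")

  none <- genotype_sample(locus4, ref4, list(), integer(0))
  expect_equal(c(none[[1]]$allele_class, none[[2]]$allele_class), c("REF", "REF"))

  het <- genotype_sample(locus4, ref4, list(del), 1L)
  expect_equal(het[[1]]$allele_class, "REF")
  expect_equal(het[[2]]$allele_class, "UNIT_LOSS")
  expect_equal(het[[2]]$unit_count, 3L)

  hom <- genotype_sample(locus4, ref4, list(del), 2L)
  expect_equal(c(hom[[1]]$allele_class, hom[[2]]$allele_class),
               c("UNIT_LOSS", "UNIT_LOSS"))
  expect_equal(hom[[1]]$unit_count, 3L)

  amb <- genotype_sample(locus4, ref4, list(del, snv), c(1L, 1L))
  expect_equal(amb[[1]]$allele_class, "AMBIGUOUS")
})

test_that("applying then reverting a variant restores the REF classification", {
  pos <- TSTART - 1
  del <- variant_record("chr15", pos, ref_base_at(ref4, pos, 5),
                        ref_base_at(ref4, pos, 1))
  alt_ref <- chng3:::apply_variant(ref4, normalize_variant(ref4, del))
  # reinserting the deleted unit recreates the 4-copy reference
  reins <- variant_record("chr15", pos, ref_base_at(alt_ref, pos, 1),
                          ref_base_at(ref4, pos, 5))
  locus3 <- repeat_locus("chr15", genomic_interval("chr15", TSTART, TSTART + 11),
                         ref_units = 3L)
  back <- call_repeat_allele(locus3, alt_ref, reins)
  expect_equal(back$allele_class, "UNIT_GAIN")
  expect_equal(back$unit_count, 4L)
  restored <- chng3:::apply_variant(alt_ref, normalize_variant(alt_ref, reins))
  expect_identical(restored$seq, ref4$seq)
})
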