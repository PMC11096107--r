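trio_with <- function(father_g, mother_g, child_g, more = NULL) {
  pedigree("f1", c("fa", "mo", "ch"), c(NA, NA, "fa"), c(NA, NA, "mo"),
           c(1, 2, 1), "unknown",
           markers = c(list(M1 = rbind(father_g, mother_g, child_g)), more))
}

test_that("Mendelian checks flag impossible children and tolerate missing data", {
  ok <- trio_with(c(1, 1), c(2, 2), c(1, 2))
  expect_equal(nrow(check_mendelian(ok)), 0L)
  bad <- trio_with(c(1, 2), c(1, 2), c(3, 3))
  v <- check_mendelian(bad)
  expect_equal(v$individual, "ch")
  expect_equal(v$marker, "M1")
  missing_parent <- trio_with(c(NA, NA), c(1, 2), c(3, 3))
  expect_equal(nrow(check_mendelian(missing_parent)), 0L)
})

test_that("de novo detection distinguishes transmission, de novo and bad parentage", {
  clean <- trio_with(c(1, 2), c(3, 4), c(1, 3))
  # carrier child, non-carrier genotyped parents, clean markers -> de novo
  expect_equal(detect_de_novo(clean, c(FALSE, FALSE, TRUE))$status, "de_novo")
  # carrier father -> transmitted
  expect_equal(detect_de_novo(clean, c(TRUE, FALSE, TRUE))$status, "transmitted")
  # ungenotyped parent -> indeterminate
  expect_equal(detect_de_novo(clean, c(NA, FALSE, TRUE))$status, "indeterminate")
  # non-carrier child
  expect_equal(detect_de_novo(clean, c(FALSE, FALSE, FALSE))$status, "non_carrier")
  # marker violations question parentage instead of calling de novo
  dirty <- trio_with(c(1, 2), c(1, 2), c(3, 3),
                     more = list(M2 = rbind(c(1, 1), c(2, 2), c(4, 4)),
                                 M3 = rbind(c(1, 1), c(1, 1), c(2, 2))))
  expect_equal(detect_de_novo(dirty, c(FALSE, FALSE, TRUE))$status,
               "parentage_questioned")
})

test_that("no child with a genotyped carrier parent is ever called de novo", {
  set.seed(8)
  for (rep in 1:20) {
    g <- lapply(1:3, function(i) {
      fa <- sample(1:4, 2, replace = TRUE)
      mo <- sample(1:4, 2, replace = TRUE)
      ch <- c(sample(fa, 1), sample(mo, 1))
      rbind(fa, mo, ch)
    })
    names(g) <- c("M1", "M2", "M3")
    ped <- trio_with(g$M1[1, ], g$M1[2, ], g$M1[3, ], more = g[2:3])
    res <- detect_de_novo(ped, c(TRUE, FALSE, TRUE), g)
    expect_equal(res$status, "transmitted")
  }
})

test_that("transmission phasing recovers a fully informative carrier haplotype", {
  # carrier father 1/2, 3/4, 5/6 at three markers; carrier haplotype is the
  # first allele of each; mother carries distinct alleles so every meiosis is
  # informative
  g <- list(M1 = rbind(c(1, 2), c(7, 8), c(1, 7)),
            M2 = rbind(c(3, 4), c(7, 8), c(3, 8)),
            M3 = rbind(c(5, 6), c(7, 8), c(5, 7)))
  ped <- pedigree("f1", c("fa", "mo", "ch"), c(NA, NA, "fa"), c(NA, NA, "mo"),
                  c(1, 2, 1), "unknown", markers = g)
  hap <- phase_carriers(ped, c(TRUE, FALSE, TRUE))
  expect_equal(unname(hap$alleles), c(1L, 3L, 5L))
  expect_equal(hap$completeness, 1)
})

test_that("homozygous carrier markers phase trivially; conflicts blank the marker", {
  g <- list(M1 = rbind(c(9, 9), c(1, 2), c(9, 1)))
  ped <- pedigree("f1", c("fa", "mo", "ch"), c(NA, NA, "fa"), c(NA, NA, "mo"),
                  c(1, 2, 1), "unknown", markers = g)
  hap <- phase_carriers(ped, c(TRUE, FALSE, TRUE))
  expect_equal(unname(hap$alleles), 9L)
  # two carrier children receiving different alleles from a het carrier parent
  g2 <- list(M1 = rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4)))
  ped2 <- pedigree("f1", c("fa", "mo", "c1", "c2"),
                   c(NA, NA, "fa", "fa"), c(NA, NA, "mo", "mo"),
                   c(1, 2, 1, 2), "unknown", markers = g2)
  hap2 <- phase_carriers(ped2, c(TRUE, FALSE, TRUE, TRUE))
  expect_true(is.na(hap2$alleles[1]))
  expect_equal(attr(hap2, "conflicts"), "M1")
})

test_that("phasing recovers simulated founder haplotypes at >= 99% of slots", {
  total <- 0L; correct <- 0L
  for (s in 1:50) {
    sim <- simulate_founder_haplotypes(k_founders = 3, n_families = 6, seed = s)
    for (f in sim$families) {
      hap <- phase_carriers(f$ped, f$carrier_status)
      truth <- sim$truth$haplotypes[f$founder_index, ]
      phased <- !is.na(hap$alleles)
      total <- total + sum(phased)
      correct <- correct + sum(hap$alleles[phased] == truth[phased])
    }
  }
  expect_gte(correct / total, 0.99)
})

test_that("founder-haplotype counting groups exact matches conservatively", {
  mk_hap <- function(fam, alleles) {
    structure(list(family = fam,
                   alleles = stats::setNames(alleles, paste0("M", seq_along(alleles))),
                   completeness = mean(!is.na(alleles))),
              class = "carrier_haplotype")
  }
  same <- list(mk_hap("a", c(1L, 2L, 3L)), mk_hap("b", c(1L, 2L, 3L)),
               mk_hap("c", c(1L, 2L, 3L)))
  expect_equal(count_founder_haplotypes(same)$k, 1L)
  # differing only at mutually missing markers -> one group (lower bound)
  fuzzy <- list(mk_hap("a", c(1L, NA, 3L)), mk_hap("b", c(1L, 2L, NA)))
  expect_equal(count_founder_haplotypes(fuzzy)$k, 1L)
  distinct <- list(mk_hap("a", c(1L, 2L, 3L)), mk_hap("b", c(1L, 2L, 4L)))
  expect_equal(count_founder_haplotypes(distinct)$k, 2L)
  # low-completeness haplotypes are excluded from the count
  sparse <- list(mk_hap("a", c(1L, NA, NA)), mk_hap("b", c(2L, 2L, 2L)))
  cnt <- count_founder_haplotypes(sparse, min_completeness = 0.5)
  expect_equal(cnt$k, 1L)
  expect_equal(cnt$excluded, "a")
  expect_equal(count_founder_haplotypes(list())$k, 0L)
})

test_that("removing markers can only merge founder-haplotype groups", {
  set.seed(31)
  for (rep in 1:10) {
    sim <- simulate_founder_haplotypes(k_founders = 4, n_families = 8,
                                       seed = 300 + rep)
    haps <- lapply(sim$families, function(f) phase_carriers(f$ped, f$carrier_status))
    k_full <- count_founder_haplotypes(haps, min_completeness = 0)$k
    drop <- sample(seq_along(haps[[1]]$alleles), 3)
    haps_sub <- lapply(haps, function(h) {
      h$alleles <- h$alleles[-drop]
      h$completeness <- mean(!is.na(h$alleles))
      h
    })
    k_sub <- count_founder_haplotypes(haps_sub, min_completeness = 0)$k
    expect_lte(k_sub, k_full)
  }
})
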