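Package: chng3
Title: Mapping Pipeline for a Noncoding Microsatellite Cause of Familial
    Thyroid Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of the computational discovery chain used
    to map familial nongoitrous congenital hypothyroidism and multinodular
    goiter to a noncoding TTTG microsatellite on chromosome 15q26.1: two-point
    parametric linkage analysis (pedigree-peeling likelihood under a fully
    penetrant autosomal dominant model), a windowed rare-variant density scan
    with one-sided Fisher tests and Bonferroni control, deterministic
    microsatellite allele genotyping with indel normalization, marker-based
    haplotype segregation and founder-haplotype counting, a chromatin
    accessibility cell-type selectivity score, and exact cohort enrichment and
    prevalence statistics. Ships seeded synthetic-data generators so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
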