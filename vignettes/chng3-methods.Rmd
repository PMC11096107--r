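---
title: "Methods and design of the chng3 pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the chng3 pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chng3)
```

# Scope

`chng3` re-implements, as reusable components, the computational chain that
maps a dominant familial thyroid phenotype (nongoitrous congenital
hypothyroidism with adult multinodular goiter, the OMIM entity CHNG3) to a
noncoding `(TTTG)n` microsatellite on chromosome 15q26.1. The chain has five
computational stages:

1. **Two-point parametric linkage** over pedigrees, giving LOD curves over the
   recombination fraction θ.
2. **A windowed rare-variant density scan** over the linkage region: 500-bp
   windows, rarity by reference-panel allele frequency, one-sided Fisher's
   exact test per window, Bonferroni control.
3. **Microsatellite allele genotyping**: locating the `(TTTG)n` tract,
   normalizing indel representation, classifying alleles.
4. **Haplotype segregation**: Mendelian checks, de novo detection,
   transmission phasing of carrier chromosomes, and counting distinct founder
   haplotypes across families.
5. **Descriptive and enrichment statistics**: exact hypergeometric tails,
   binomial proportions with intervals, prevalence inversion, Welch's t.

Raw patient genomes and array genotypes behind the original analysis are
access-restricted, so every stage is paired with a seeded synthetic-data
generator that reproduces the statistical structure the stage assumes. All
coordinates are 1-based inclusive internally; 0-based half-open conversion
happens only at the bedGraph boundary.

# The linkage model

The disease model is autosomal dominant with full penetrance, no phenocopies,
and disease allele frequency $10^{-4}$ (`linkage_model()`). Penetrance is a
triple $f = (f_0, f_1, f_2)$ over disease-allele counts, default $(0, 1, 1)$;
$f_0$ is the phenocopy rate. The default analysis is *affected-only*:
unaffected phenotypes are treated as unknown, which makes the LOD robust to
incomplete or age-dependent penetrance — relevant here because the phenotype
is age-dependent.

The likelihood of a pedigree at recombination fraction θ treats each
individual's latent state as an ordered pair of disease–marker haplotypes.
Founder pairs get Hardy–Weinberg priors with linkage-equilibrium haplotype
frequencies (product of disease and marker allele frequencies — the standard
LINKAGE convention; nothing in the source analysis suggests otherwise).
Transmission from a parent with haplotypes $(h_1, h_2)$ emits each parental
haplotype with probability $(1-\theta)/2$ and each recombinant with
$\theta/2$, sex-averaged. Observed marker genotypes enter as indicator
factors on the unordered allele pair; phenotypes as penetrance factors;
unknown phenotype contributes 1.

`pedigree_log_likelihood()` evaluates this sum exactly by variable
elimination over the pedigree factor graph — peeling in the Elston–Stewart
tradition, with the elimination of a leaf child over its two parents done as
a closed-form matrix product for speed. Each elimination rescales the
intermediate factor and accumulates the shift in log10, so deep pedigrees
cannot underflow. Pedigrees with marriage or inbreeding loops are rejected
(`unsupported structure`) rather than broken: correctness over coverage at
this scale. `brute_force_log_likelihood()` is a deliberately independent
oracle — depth-first enumeration of all joint haplotype-pair assignments in
parents-before-children order with zero-weight pruning, capped at 10 members —
used throughout the tests to pin the peeling implementation to machine
accuracy.

`lod_curve()` reports $LOD(\theta) = \log_{10} L(\theta) - \log_{10} L(0.5)$
on a grid (default $0, 0.01, \dots, 0.5$; the grid must contain 0.5, where
the curve is zero by construction). Two-point analysis was chosen over
multipoint deliberately: the original study delegated multipoint computation
to an external service, and a two-point engine preserves the model while
remaining verifiable against exhaustive enumeration. The printed family-A
maximum LOD (4.8) depends on unpublished genotypes and is therefore not a
quantity this package can recompute; the likelihood machinery is validated
instead by the oracle equivalence, the exact $n \log_{10} 2$ closed form on
phase-known non-recombinant fixtures, and parameter recovery
(θ̂ within ±0.05 of the generating θ at 0, 0.1 and 0.3 over 200 simulated
six-children nuclear families each — sizes chosen so the whole experiment
runs in a couple of minutes while leaving the Monte-Carlo error of θ̂ near
0.02).

# The rare-variant density scan

`make_bins()` partitions a region into consecutive left-aligned windows
(default 500 bp), truncating the last window; over the published scan region
chr15:86,206,001–89,412,500 this yields exactly 6,413 full windows, and the
Bonferroni threshold is $\alpha/m = 0.05/6413 \approx 7.8\times10^{-6}$.
A variant is *rare* iff its panel allele frequency is strictly below 0.002;
variants absent from the panel count as frequency 0. Keys are matched on the
normalized (left-aligned, parsimonious) `chrom:pos:ref:alt` form so that
indel representation differences cannot split a shared allele between cohort
and panel.

The per-window 2×2 table counts *individuals* (carrier = at least one
non-missing alternate allele at any rare variant in the window) per group,
so rows always sum to group sizes and a person with several variants in one
window counts once. The source describes comparing "density of rare
variants" without fixing the table construction; an allele-counting mode
(`unit = "alleles"`, chromosome denominators) is provided as a config switch
but is not the default. Related individuals are counted independently, as
the published cohort of 25 patients from 11 families apparently was; no
kinship adjustment is applied. Missing genotypes never make carriers and
never shrink denominators. The one-sided direction is enrichment in cases.

P-values come from `fisher_exact_one_sided()`, an upper-tail hypergeometric
sum accumulated in log space via `lgamma`, which stays exact to hundreds of
thousands of log units below double underflow; a direct double-precision
summation mode serves as an internal cross-check (they agree to 12
significant digits for table totals up to 1,000), and R's `fisher.test` is
used as an external oracle in the tests.

# The synthetic cohort

`cohort_sim_config()` defaults *are* the study conditions: 25 cases vs 56
controls over the 3.2-Mb region; background rare variants private (one
heterozygous carrier each), placed uniformly at 0.0094 expected variants per
individual per kb — the density implied by 2,446 rare variants across 81
genomes over 3,206.5 kb; one spiked window at the bin containing position
88,569,434, whose shared deletion-style variant is carried by each case with
probability 0.7 (the shared deletion was found in 8 of 11 unsolved case
families) and by no controls; panel frequencies uniform below the 0.002
cutoff with 30% of variants absent from the panel. Private background
variants keep per-window null tables clean; real cohorts have linkage
disequilibrium, mutation-rate heterogeneity and relatedness that the
generator does not model, so passing recovery tests demonstrates correctness
of the machinery under the stated model, not robustness to those real-data
features.

Null calibration (no spike) runs on a 250-kb subregion — 500 windows — purely
to keep 200 replicates fast; rates and window size are unchanged. The
family-wise false-positive rate over 200 null cohorts stays at or below α
(Fisher's exact test is conservative at these tiny counts, so the observed
rate is essentially 0), and the spiked window is ranked first in ≥95 of 100
seeded cohorts at the default spike strength.

# Microsatellite genotyping

Indel representation inside a repeat tract is ambiguous; `normalize_variant()`
produces the canonical parsimonious left-aligned form (trim shared suffix,
borrowing reference bases leftward when an allele would empty; then trim the
shared prefix to one anchor base). Left alignment is the common normalization
convention; published coordinates for the deletion are right-shifted, and the
normalizer maps either representation to the same key.

`find_repeat_tract()` counts *perfect* tandem copies only — the maximal
perfect run covering the anchor, scanning all unit phases (the unit must not
be self-periodic, so runs in different phases cannot overlap). An internal
substitution therefore shortens the perfect run; the classifier, not the
count, carries the interpretation. `call_repeat_allele()` applies the variant
and re-locates the tract: a pure unit-multiple length change whose alternate
sequence equals the reference with the tract resized classifies as
`UNIT_LOSS`/`UNIT_GAIN` (the equality test makes the verdict independent of
indel placement); a single-base substitution inside the tract is
`SNV_DISRUPTED`; everything else in scope is `OTHER`, and variants beyond the
±100-bp flank window return `OUT_OF_SCOPE` rather than raising. Diplotypes
follow zygosity; two unphased in-scope variants give `AMBIGUOUS`.

The packaged reference around the tract is synthetic: random non-repetitive
flanks are redrawn until the tract is the maximal perfect run at the printed
coordinates (`make_repeat_locus_reference()`, labelled synthetic in its
documentation). Only plus-strand sequences are processed.

# Haplotype segregation

Phasing is rule-based transmission tracing, not likelihood reconstruction:
in every carrier-parent→carrier-child meiosis the allele the carrier parent
transmitted (resolved by subtracting the other parent's possible
contribution) is assigned to the carrier haplotype, and any carrier's
homozygous marker phases trivially. Contradictory evidence across meioses —
recombination or genotyping error — blanks the marker and logs a conflict;
no recombination is modelled inside the small marker window. Founder
counting groups families by exact match on jointly non-missing alleles.
Because missing data can only merge groups, the count is a lower bound
("at least k"), matching how the original study phrases its four founder
haplotypes; the exact-match rule (no stepwise-mutation tolerance) is this
package's documented choice where the source does not state one.
`detect_de_novo()` only calls a de novo acquisition when both parents are
genotyped non-carriers *and* the marker panel shows no Mendelian violation;
violations downgrade the call to `parentage_questioned`.

# Cell-type selectivity

The selectivity of a region for a target cell type is the target's median
binned read depth over the region divided by the sum of all cell types'
medians (the published definition, with 100-bp bins). Bins are anchored at
each track's declared interval start, matching a precomputed-bins workflow;
query regions include partially overlapping bins whole, and an even number
of bins takes the midpoint median. Scores over cell types sum to 1 whenever
any signal exists and are invariant to common rescaling; an all-zero region
is flagged undefined rather than erroring. The 154 cell types of the public
atlas are a default, not a constant. On the noise-free fixture (baseline 1,
target peak +153) the peak selectivity is exactly $154/307$.

# Cohort statistics

Confidence intervals default to Wilson score intervals, with
Clopper–Pearson available; the published intervals (11.9–16.1% for 137/989;
1/5,400–1/35,500 for the prevalence) do not exactly match either standard
method and their method is unreported, so outputs always label the method
used and no test asserts the printed bounds. Prevalence inverts the carrier
proportion and rounds to 3 significant figures (3/38,722 → 1 in 12,900).
The giant-cohort comparison printed as $P < 10^{-300}$ is reproducible only
as an exact log10 tail (the printed form suggests downstream underflow) and
is not asserted anywhere. Welch's t (two-sided, Welch–Satterthwaite degrees
of freedom) handles the reporter-assay style comparisons; zero-variance
degenerate inputs resolve deterministically. The packaged luciferase table
is a synthetic fixture with control mean 1.0 and repressor-construct mean
0.68 (a 32% reduction with ~6% spread), shipped as demo input only.

# Numerical choices and degenerate inputs

* Likelihood peeling rescales factors after every elimination; log10 shifts
  accumulate exactly, and `-Inf` (with a diagnostic) is returned for
  Mendelian-impossible data instead of an error.
* Scan ranking breaks p-value ties by genomic position; windows with no case
  carriers short-circuit to $p = 1$ (the upper tail from zero is 1).
* `LOD(0.5)` is set to zero identically (it is the definition, and setting it
  avoids `-0` artifacts); `-Inf` LOD at θ = 0 is legitimate when an obligate
  recombinant exists.
* All generators run under a saved-and-restored RNG state, so they are pure
  functions of `(config, seed)` and never disturb the caller's stream;
  sub-stage seeds are fixed offsets of the master seed.
* Problem sizes in the validation suite — 200 pedigrees per θ point, 200 null
  cohorts on 500 windows, 100 oracle pedigrees of up to 10 members — were
  chosen once as the smallest sizes at which the Monte-Carlo noise is well
  inside the asserted bands.

# Known limitations

Two-point linkage only; loop-free pedigrees only; no sex-specific
recombination; no kinship adjustment in the scan; perfect-copy repeat
counting (no stutter modelling); rule-based phasing without recombination
handling inside the panel; synthetic flanking sequence rather than the true
GRCh38 context (coordinates preserved). These mirror the boundaries of what
the published numbers let an independent implementation verify.
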