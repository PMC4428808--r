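---
title: "Quantifying allele-specific expression with personalized diploid alignment"
author: "asequant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific expression with personalized diploid alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asequant)
```

## The problem

Allele-specific expression (ASE) is unequal RNA output of the two alleles
at a heterozygous locus within one individual. It is measured by counting,
at each heterozygous SNP, how many RNA-seq reads carry the reference
versus the alternate allele. Two systematic problems make naive counting
unreliable:

* **Reference bias.** Against a single universal reference, a read
  carrying the alternate allele incurs at least one extra mismatch, so it
  is more likely to fail alignment or be out-competed. Reference-allele
  reads are therefore over-counted and balanced loci drift toward
  apparent reference over-expression.
* **Sampling noise.** At typical testing depths (tens of reads) the
  binomial sampling variance of the reference fraction is large, and per-SNP
  ASE calls replicate poorly between technical replicates.

The workflow implemented here addresses the first problem with
personalized diploid alignment plus strict alignment quality control, and
the second with a combined effect-size/significance classifier and
haplotype-phased aggregation of SNPs into gene-level tests.

## The model and procedure

### Personalized diploid alignment

Phased heterozygous and homozygous-alternate SNPs are substituted into
the universal reference to build two haplotype genomes
(`build_haplotype_sequence()`). Substitution is SNP-only, so the three
reference spaces are coordinate-identical; haplotype A is labeled
"maternal" and B "paternal" purely as labels. Reads are aligned (outside
this package) against all three references, and `merge_alignment_sets()`
selects one alignment per read pair:

1. a candidate with a fully mapped pair beats any candidate with an
   unmapped mate;
2. among equally mapped candidates the smallest sum of edit distances
   (SAM `NM` over mapped mates) wins;
3. ties go to the universal alignment.

The spec of the selection rules leaves one case open: a maternal/paternal
tie when universal is absent or worse. We resolve it to maternal,
deterministically, and report it as a tied minimum
(`"fewest_mismatches"`). Chosen records carry their origin in a `ZR`
tag. `filter_alignments()` then removes PCR duplicates (identical contig,
unclipped start, strand and mate start; best-MAPQ pair kept, ties to the
first encountered — the standard coordinate criterion, re-implemented
here because the original pipeline delegated it to an external tool),
multi-mapped records, records with MAPQ < 9, and mitochondrial records.

### WGS heterozygosity verification

Variants are only trusted for ASE testing when DNA evidence supports
heterozygosity. Reads contribute to verification when aligned length
(CIGAR `M`) ≥ 34, MD substitutions ≤ 4 and `SM` > 10 (the `SM` tag is
BWA-specific, so behaviour on missing tags is configurable:
treat-as-fail by default). A SNP is heterozygous when the alternate
count exceeds 3 at depth ≤ 12, exceeds 4 at depth 13–30, or reaches 25%
of reads at depth ≥ 31; depth is the ref+alt count of called alleles,
third alleles excluded. Indels are dropped near homopolymers of ≥ 7
bases, in annotated repeats, or at length ≥ 200, and are heterozygous
when the supporting/informative read ratio lies in [0.2, 0.7]. The
printed rule does not state whether the ratio bounds are open or closed;
we read them as inclusive and expose them as a parameter.

### SNP-level classification

`pileup_counts()` counts every mapped, de-duplicated record overlapping
a phased heterozygous SNP (no base-quality threshold, overlapping mates
both counted, matching a permissive mpileup configuration). A SNP is
*testable* at ≥ 10 unique reads; the testability depth includes
third-allele bases, while the reference fraction denominator is ref+alt
only (both choices configurable — the source rule is ambiguous on both
points).

The expected reference fraction of a SNP is not 0.5 but the median
observed reference fraction of its *ordered genotype* (the specific
reference→alternate base pair, 12 values) in the same library
(`compute_bin_medians()`); bins empty at small scale fall back to the
library-wide median. A testable SNP is classified ASE when **both**

* |observed − expected reference fraction| > 0.15, and
* the two-sided binomial probability of its reference count at the
  expected fraction is ≤ 0.05.

The two criteria complement each other: the p-value alone would flag
highly expressed SNPs with trivial imbalance, the effect size alone
would flag lowly expressed SNPs whose imbalance is sampling noise. At
depth 10 against an expected fraction of 0.5 the classifier calls ASE
exactly for reference counts {0, 1, 9, 10}, giving a truly-balanced-site
ASE rate of 22/1024 ≈ 2.15% — an analytic operating point the test
suite verifies by simulation.

The two-sided construction is not stated in the source; we default to
the minimum-likelihood convention (sum of all outcome probabilities not
exceeding that of the observed count, the convention of
`stats::binom.test`), which is well defined for asymmetric expectations,
and provide tail-doubling as an alternative. Direction of imbalance is
reported against haplotype, not reference, so cross-SNP comparisons are
phase-aware.

### Alignment-confounder QC

Un-phased variants — absent from the haplotype references — still cause
local alignment errors. Testable SNPs are removed when an un-phased
heterozygous indel lies within 100 bp (distance to the nearest edge of
the indel's reference-affected interval, not the VCF anchor), when 4 or
more un-phased heterozygous SNPs lie within 100 bp, or when alignability
is below 1. "Within 100 bp" is inclusive. The proximal-SNP count covers
un-phased SNPs by default (those are what the removal rule names) with
an option to include phased ones. Positions covered by no alignability
interval score 0 (unknown mappability is treated as bad).
`binned_ase_proportion()` exposes the confounders: it bins classified
SNPs by any covariate (distances, counts, alignability, imputation R²,
transcript feature) and tests each bin against the global ASE proportion
with an exact binomial test (the diagnostic in the source prints
p-values without naming a test; the exact binomial is the natural
choice for a proportion against a fixed reference value).

### Locus-level aggregation

`aggregate_gene_ase()` groups QC-passing testable SNPs by annotated gene
span (the "genic boundaries"; exonic status is tracked separately), sums
haplotype-A and haplotype-B counts over member SNPs, and applies the
two-sided binomial test to the sums with expected proportion 0.5 —
haplotype sums mix ordered genotypes and diploid alignment removes
reference bias, so no per-genotype baseline applies (a pooled-median
alternative is configurable). Genes are ranked by p-value, ties broken
by absolute haplotype difference then gene id for deterministic output.
Phase concordance is true when all member SNPs lean toward the same
haplotype; exactly balanced SNPs are neutral (the source is silent on
them; a balanced SNP carries no directional evidence).
`flag_gene_criteria()` adds the replication tiers: ≥ 2 testable exonic
SNPs in both replicates, presence of a *replicated ASE SNP* (the same
site ASE in both replicates), per-replicate concordance.
`map_snps_to_isoforms()` assigns testable SNPs to transcripts through
exon overlap, dropping transcripts without a testable exonic SNP, so
discordant per-isoform direction summaries can expose allele-specific
isoform regulation.

Where replicates exist, results are computed per replicate and the
comparison table (`compare_replicates()`) reports the 2×2 ASE agreement
and reference-fraction correlation at rising depth thresholds; pooling
counts across replicates is left to the caller since the source reports
per-replicate flags alongside averaged displays.

## The synthetic-data generator

Every stage is validated against simulated diploid data with fully known
truth (`sim_config()` and friends). The generator emulates: a small
multi-exon genome with CDS/UTR/intron structure and an exon-skipping
second isoform per gene; phased het and hom-alt SNPs with a configurable
un-phased fraction; un-phased intronic/intergenic indels; stranded FR
read pairs drawn from the two haplotype sequences with per-gene allelic
ratios, substitution sequencing errors, and exact per-space edit
distances; and an aligner mismatch tolerance (`max_mismatches`, default
2 on 100 bp reads) under which a mate exceeding the tolerance in a given
reference space is unmapped there. That last mechanism is what creates
reference bias in universal-only alignment — variant-dense reads drop
out — and diploid merging recovers them, which the test suite checks as
a property (universal-only pooled reference fraction > 0.5; merged
within 3 binomial SE of 0.5 with at least as many informative reads).

Deliberate simplifications, and what they imply for the tests:

* Reads are ungapped within single exons: no splicing, no indels in
  reads, so the alignment oracle is exact and pileup base extraction is
  error-free. Consequences of spliced alignment are represented only
  through the proximity-filter window, not simulated.
* Indels are planted outside exons only, keeping haplotype genomes
  coordinate-identical (SNP-only personalization, as in the workflow the
  package implements).
* Base errors are substitutions; no quality strings, PCR duplicates
  beyond exact coordinate duplicates, or coverage waviness.

Passing tests therefore demonstrate the *decision rules* and their
statistical operating characteristics, not robustness to gapped
alignment artifacts or base-quality miscalibration in real data.

Variant placement enforces a ≥ 2 bp spacing by keeping the earlier of
any adjacent pair; a `snp_rate` above 0.25 raises a position-collision
error because spaced variants can no longer be hosted. Default
conditions (100 bp reads, 400 bp exons, per-base SNP rate 0.002, 80%
heterozygous, 10% withheld from phasing, ~30 pairs of coverage per SNP,
0.1% base error) are chosen to resemble a dense, well-covered human
locus while keeping test runtimes in seconds; individual scenarios
override them (for example the reference-bias demonstration uses SNP
rate 0.04 and error 0 so that the bias mechanism is strong and exactly
attributable, and the gene-recovery scenario uses 21 genes with one
planted at allelic ratio 0.9 and ≥ 200 haplotype reads).

## Numerical choices and degenerate inputs

* Binomial p-values are computed by direct enumeration of
  `dbinom(0:n, n, p)` with a `1 + 1e-7` relative slack against
  floating-point ties (the `binom.test` convention); identical
  (k, n, p) triples are evaluated once. Expected fractions of exactly
  0 or 1 are rejected rather than patched.
* Ordered-genotype medians use `stats::median` over testable sites; a
  library with no testable site is an error, an unpopulated genotype bin
  falls back to the library median.
* `choose_alignment()` on a triple with no mapped mate anywhere returns
  universal (when supplied) with reason `only_candidate`; malformed NM
  tags demote a record to unmapped with a warning rather than aborting
  a merge.
* Duplicate-removal ties keep the first record encountered, making
  reruns byte-identical.
* Gene ranking ties are broken by |hapA − hapB| then gene id.

## Limitations

The package consumes alignments; it does not run an aligner, so the
`max_mismatches` abstraction stands in for real aligner behaviour
(soft-clipping, splice-aware scoring) in simulation only. Personalized
genomes are SNP-only — indel-aware personalization and coordinate
lift-over are out of scope. Hemizygous and sex-chromosome sites are
treated like any other contig, as the source workflow does not specify
special handling. The beta-binomial overdispersion family of models is
deliberately not used: the classifier follows the simple-binomial +
effect-size design it implements, whose conservatism comes from pairing
the two criteria rather than from modelling extra-binomial variance.

## Problem sizes used by the test suite

Unit tests run on 20 kb toy genomes with 2 genes and hundreds of read
pairs. The statistical checks use 100,000 direct binomial draws for the
classifier operating points, 21 genes / ~25,000 read pairs for gene
recovery, ten 2,000-site replicate pairs for the depth-threshold trend,
and exhaustive enumeration (all depths 1–100 for the heterozygosity
rules; all 15,625 mapped-state × edit-distance triples for alignment
selection). These sizes give the property checks 3-standard-error
resolution while completing in well under a minute each.
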