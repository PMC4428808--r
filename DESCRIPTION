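Package: asequant
Title: Allele-Specific Expression Quantification with Personalized
    Diploid Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@asequant.org",
           role = c("aut", "cre"))
Description: Quantifies allele-specific expression (ASE) from RNA-seq data
    aligned against personalized diploid references. Builds per-haplotype
    genome sequences from phased SNPs, merges maternal/paternal/universal
    alignment sets by edit-distance optimality to remove reference bias,
    verifies heterozygosity against whole-genome sequencing with heuristic
    rules, counts allele-resolved coverage at phased heterozygous SNPs,
    classifies per-SNP ASE with ordered-genotype median baselines and a
    two-sided binomial test plus an effect-size rule, removes SNPs
    confounded by proximal un-phased variants or poor alignability, and
    aggregates haplotype-phased counts into gene- and isoform-level ASE.
    Includes a synthetic diploid data generator with known allelic truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
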