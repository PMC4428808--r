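#' Configuration for the synthetic diploid data generator
#'
#' Collects and validates all parameters of the toy diploid genome, variant
#' and read simulators. The same seed always yields byte-identical output.
#'
#' @param genome_length total genome size in bases, split evenly across
#'   contigs.
#' @param n_contigs number of contigs.
#' @param n_genes number of non-overlapping gene models to place.
#' @param exons_per_gene exons per gene model.
#' @param snp_rate per-base probability that a SNP is planted.
#' @param indel_count number of un-phased heterozygous indels planted in
#'   intronic/intergenic sequence.
#' @param het_fraction proportion of planted SNPs that are heterozygous
#'   (the remainder are homozygous-alternate).
#' @param read_length read length in bases.
#' @param fragment_depth target mean read-pair coverage per expressed SNP.
#' @param base_error_rate per-base substitution sequencing-error
#'   probability.
#' @param allelic_ratio_map named numeric vector mapping gene id to the
#'   true haplotype-A expression fraction in `[0, 1]`; genes absent from the
#'   map are balanced (0.5).
#' @param unphased_fraction proportion of heterozygous SNPs withheld from
#'   phasing (these are the un-phased confounders the QC module screens
#'   for).
#' @param seed integer RNG seed.
#' @param exon_length,intron_length exon and intron sizes (bases) of the
#'   generated gene models.
#' @param max_mismatches aligner tolerance: a mate whose true edit distance
#'   against a given reference space exceeds this value is emitted as
#'   unmapped in that alignment set. This is what makes variant-carrying
#'   reads drop out of universal-only alignment and creates reference bias.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(genome_length = 10000, n_genes = 2, seed = 1)
#' @export
sim_config <- function(genome_length = 20000L,
                       n_contigs = 1L,
                       n_genes = 2L,
                       exons_per_gene = 3L,
                       snp_rate = 0.002,
                       indel_count = 2L,
                       het_fraction = 0.8,
                       read_length = 100L,
                       fragment_depth = 30,
                       base_error_rate = 0.001,
                       allelic_ratio_map = NULL,
                       unphased_fraction = 0.1,
                       seed = 1L,
                       exon_length = 400L,
                       intron_length = 150L,
                       max_mismatches = 2L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_contigs = as.integer(n_contigs),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    snp_rate = snp_rate,
    indel_count = as.integer(indel_count),
    het_fraction = het_fraction,
    read_length = as.integer(read_length),
    fragment_depth = fragment_depth,
    base_error_rate = base_error_rate,
    allelic_ratio_map = allelic_ratio_map,
    unphased_fraction = unphased_fraction,
    seed = as.integer(seed),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    max_mismatches = as.integer(max_mismatches)
  )
  for (f in c("snp_rate", "het_fraction", "base_error_rate",
              "unphased_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single value in [0, 1]", f))
  }
  if (cfg$read_length <= 0L) stop("'read_length' must be positive")
  if (cfg$genome_length <= 0L) stop("'genome_length' must be positive")
  if (cfg$n_contigs <= 0L) stop("'n_contigs' must be positive")
  if (cfg$n_genes < 0L) stop("'n_genes' must be non-negative")
  if (cfg$exons_per_gene < 1L) stop("'exons_per_gene' must be >= 1")
  if (cfg$indel_count < 0L) stop("'indel_count' must be non-negative")
  if (cfg$fragment_depth < 0) stop("'fragment_depth' must be non-negative")
  if (cfg$exon_length < 2L * cfg$read_length + 10L)
    stop("'exon_length' must allow an ungapped read pair: need >= ",
         2L * cfg$read_length + 10L, " bases")
  if (!is.null(cfg$allelic_ratio_map)) {
    arm <- cfg$allelic_ratio_map
    if (is.null(names(arm)) || any(!nzchar(names(arm))))
      stop("'allelic_ratio_map' must be a named numeric vector")
    if (any(arm < 0 | arm > 1))
      stop("allelic ratios must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$genome_length, "bp /", x$n_contigs, "contig(s),",
      x$n_genes, "gene(s), snp_rate", x$snp_rate,
      ", seed", x$seed, "\n")
  invisible(x)
}
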