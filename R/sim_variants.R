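#' Plant phased and un-phased variants in a toy reference
#'
#' Samples SNP positions at `snp_rate`, assigns zygosity and haplotype
#' phase, withholds a configured fraction of heterozygous SNPs from phasing
#' (the un-phased confounder set), and plants un-phased heterozygous indels
#' in intronic/intergenic sequence only, so the haplotype genomes remain
#' coordinate-identical to the reference.
#'
#' @param reference output of [generate_toy_reference()].
#' @param config the [sim_config()] used (or a compatible one).
#' @return a list with elements
#'   \describe{
#'     \item{phased}{data.frame of phased variants (contig, pos, ref, alt,
#'       zygosity, hap_a, hap_b, r_squared, source, wgs_verified, class).}
#'     \item{unphased_snvs}{data.frame of withheld heterozygous SNPs.}
#'     \item{indels}{data.frame of un-phased indels (VCF-style ref/alt,
#'       type, length).}
#'     \item{truth}{data.frame of per-het-SNP truth: gene membership,
#'       exonic flag, haplotype carrying the reference allele, true
#'       reference fraction implied by the gene's allelic ratio, and
#'       whether the SNP was phased.}
#'   }
#' @export
plant_phased_variants <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  seqs <- as_seq_chars(reference$genome)

  vars <- list()
  for (ctg in names(seqs)) {
    L <- nchar(seqs[[ctg]])
    if (config$snp_rate > 0.25)
      stop("position collision: 'snp_rate' of ", config$snp_rate,
           " cannot host non-adjacent variants; lower the rate")
    pos <- which(runif(L) < config$snp_rate)
    pos <- pos[pos > 2L & pos < L - 1L]
    # enforce a >= 2 bp spacing so variants never collide: keep the
    # earlier of any adjacent pair
    if (length(pos) > 1L) {
      keep <- c(TRUE, diff(pos) >= 2L)
      while (!all(keep)) {
        pos <- pos[keep]
        keep <- c(TRUE, diff(pos) >= 2L)
      }
    }
    if (!length(pos)) next
    ref <- substring(seqs[[ctg]], pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                  character(1), USE.NAMES = FALSE)
    vars[[ctg]] <- data.frame(contig = ctg, pos = pos, ref = ref, alt = alt,
                              stringsAsFactors = FALSE)
  }
  snps <- if (length(vars)) do.call(rbind, vars) else
    data.frame(contig = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  n <- nrow(snps)

  is_het <- runif(n) < config$het_fraction
  ref_on_hap <- ifelse(sample(c(TRUE, FALSE), n, replace = TRUE), "A", "B")
  unphased <- is_het & (runif(n) < config$unphased_fraction)

  snps$zygosity <- ifelse(is_het, "het", "hom_alt")
  snps$hap_a <- ifelse(is_het,
                       ifelse(ref_on_hap == "A", snps$ref, snps$alt),
                       snps$alt)
  snps$hap_b <- ifelse(is_het,
                       ifelse(ref_on_hap == "B", snps$ref, snps$alt),
                       snps$alt)
  snps$r_squared <- round(0.5 + 0.5 * runif(n), 3)
  snps$source <- sample(c("array", "imputed"), n, replace = TRUE,
                        prob = c(0.3, 0.7))
  snps$wgs_verified <- TRUE
  snps$class <- "snp"

  phased <- snps[!unphased, , drop = FALSE]
  unphased_snvs <- snps[unphased, , drop = FALSE]
  unphased_snvs$hap_a <- rep(NA_character_, nrow(unphased_snvs))
  unphased_snvs$hap_b <- rep(NA_character_, nrow(unphased_snvs))

  indels <- plant_indels(reference, config, seqs, snps$pos, snps$contig)

  truth <- snp_truth(snps[is_het, , drop = FALSE],
                     ref_on_hap[is_het], !unphased[is_het],
                     reference, config)

  list(phased = phased, unphased_snvs = unphased_snvs, indels = indels,
       truth = truth)
}

# un-phased het indels restricted to intronic/intergenic positions
plant_indels <- function(reference, config, seqs, taken_pos, taken_ctg) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (config$indel_count == 0L) return(empty)
  feats <- reference$features
  exon <- feats[feats$feature == "exon", , drop = FALSE]
  out <- empty
  tries <- 0L
  while (nrow(out) < config$indel_count) {
    tries <- tries + 1L
    if (tries > 200L * config$indel_count)
      stop("could not place ", config$indel_count,
           " intronic/intergenic indels; genome too small or too genic")
    ctg <- sample(names(seqs), 1L)
    L <- nchar(seqs[[ctg]])
    len <- sample(1:10, 1L)
    pos <- sample(seq(5L, L - len - 5L), 1L)
    in_exon <- any(exon$contig == ctg & exon$start <= pos + len &
                     exon$end >= pos)
    near_variant <- any(taken_ctg == ctg & abs(taken_pos - pos) < 2L) ||
      any(out$contig == ctg & abs(out$pos - pos) < len + 2L)
    if (in_exon || near_variant) next
    type <- sample(c("ins", "del"), 1L)
    anchor <- substring(seqs[[ctg]], pos, pos)
    if (type == "del") {
      ref <- substring(seqs[[ctg]], pos, pos + len)
      alt <- anchor
    } else {
      ref <- anchor
      alt <- paste0(anchor,
                    paste(sample(DNA_BASES, len, replace = TRUE),
                          collapse = ""))
    }
    out <- rbind(out, data.frame(contig = ctg, pos = pos, ref = ref,
                                 alt = alt, type = type, length = len,
                                 stringsAsFactors = FALSE))
  }
  out[order(out$contig, out$pos), , drop = FALSE]
}

# ground truth per heterozygous SNP
snp_truth <- function(het, ref_on_hap, phased_flag, reference, config) {
  genes <- reference$genes
  exon <- reference$features[reference$features$feature == "exon", ,
                             drop = FALSE]
  gene_id <- rep(NA_character_, nrow(het))
  exonic <- rep(FALSE, nrow(het))
  for (i in seq_len(nrow(het))) {
    hit <- which(genes$contig == het$contig[i] &
                   genes$start <= het$pos[i] & genes$end >= het$pos[i])
    if (length(hit)) gene_id[i] <- genes$gene_id[hit[1]]
    exonic[i] <- any(exon$contig == het$contig[i] &
                       exon$start <= het$pos[i] & exon$end >= het$pos[i])
  }
  ratio <- rep(0.5, nrow(het))
  if (!is.null(config$allelic_ratio_map)) {
    known <- gene_id %in% names(config$allelic_ratio_map)
    ratio[known] <- unname(config$allelic_ratio_map[gene_id[known]])
  }
  true_rf <- ifelse(is.na(gene_id) | !exonic, NA_real_,
                    ifelse(ref_on_hap == "A", ratio, 1 - ratio))
  data.frame(contig = het$contig, pos = het$pos, ref = het$ref,
             alt = het$alt, gene_id = gene_id, exonic = exonic,
             ref_on_hap = ref_on_hap, true_allelic_ratio = ratio,
             true_ref_fraction = true_rf, phased = phased_flag,
             stringsAsFactors = FALSE)
}
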