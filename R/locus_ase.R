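#' Aggregate SNP calls into gene-level allele-specific expression
#'
#' Groups QC-passing testable SNP calls by annotated genic boundaries
#' (gene span membership; exonic status is tracked separately), sums the
#' haplotype-A and haplotype-B read counts over member SNPs, and tests
#' the summed counts with a two-sided binomial test against an expected
#' proportion of 0.5 (haplotype sums mix ordered genotypes, and diploid
#' alignment removes reference bias, so no per-genotype baseline
#' applies). The summed counts have far more power than any single SNP
#' and dampen per-SNP sampling noise. Genes are ranked from most to least
#' imbalanced (p-value, ties by absolute haplotype difference then gene
#' id).
#'
#' @param calls classified calls (see [classify_snp_ase()]); rows with
#'   class "untestable" or without phase are ignored.
#' @param genes gene span data.frame (gene_id, contig, start, end).
#' @param qc optional QC verdict data.frame aligned with `calls` (see
#'   [apply_qc_filters()]); failing rows are excluded.
#' @param expected expected haplotype-A proportion (default 0.5).
#' @return data.frame, one row per gene with at least one member SNP:
#'   gene_id, n_testable_snps, hap_a_sum, hap_b_sum, hap_a_fraction,
#'   p_value, concordant, rank; sorted by rank.
#' @export
aggregate_gene_ase <- function(calls, genes, qc = NULL, expected = 0.5) {
  use <- calls$class %in% c("ASE", "not_ASE") &
    !is.na(calls$hap_a_count) & !is.na(calls$hap_b_count)
  if (!is.null(qc)) use <- use & qc$pass
  calls <- calls[use, , drop = FALSE]

  rows <- lapply(seq_len(nrow(genes)), function(g) {
    m <- calls$contig == genes$contig[g] &
      calls$pos >= genes$start[g] & calls$pos <= genes$end[g]
    if (!any(m)) return(NULL)
    a <- sum(calls$hap_a_count[m])
    b <- sum(calls$hap_b_count[m])
    pv <- if (a + b > 0)
      binomial_two_sided(a, a + b, expected) else NA_real_
    data.frame(gene_id = genes$gene_id[g], n_testable_snps = sum(m),
               hap_a_sum = a, hap_b_sum = b,
               hap_a_fraction = if (a + b > 0) a / (a + b) else NA_real_,
               p_value = pv,
               concordant = phase_concordance(calls$direction[m]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(gene_id = character(0), n_testable_snps = integer(0),
                      hap_a_sum = integer(0), hap_b_sum = integer(0),
                      hap_a_fraction = numeric(0), p_value = numeric(0),
                      concordant = logical(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  ord <- order(out$p_value, -abs(out$hap_a_sum - out$hap_b_sum),
               out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Phase concordance of imbalance directions within a gene
#'
#' TRUE when every member SNP's imbalance direction is identical;
#' balanced SNPs (equal haplotype counts) are neutral and do not break
#' concordance. A single SNP is vacuously concordant.
#'
#' @param directions character vector of "toward_hapA" / "toward_hapB" /
#'   "balanced" (NAs ignored).
#' @return logical scalar.
#' @examples
#' phase_concordance(c("toward_hapA", "toward_hapA"))  # TRUE
#' phase_concordance(c("toward_hapA", "toward_hapB"))  # FALSE
#' @export
phase_concordance <- function(directions) {
  d <- directions[!is.na(directions) & directions != "balanced"]
  length(unique(d)) <= 1L
}

#' Replication and stringency flags for gene-level ASE
#'
#' Combines two technical replicates' SNP call sets into per-gene flags:
#' whether the gene holds at least two testable exonic SNPs in both
#' replicates, whether it contains a replicated ASE SNP (the same site
#' classified ASE in both replicates), and per-replicate phase
#' concordance. The four stringency tiers (replicated-ASE-SNP and/or
#' concordance required) are derivable from these flags.
#'
#' @param calls_rep1,calls_rep2 classified calls per replicate (may share
#'   or differ in site universe). A missing replicate (`NULL`) yields
#'   flags computed on the available data with `partial = TRUE`.
#' @param genes gene span data.frame.
#' @param exonic_rep1,exonic_rep2 logical vectors flagging exonic sites,
#'   aligned with the call tables (from [annotate_feature()]; exonic
#'   means a coding_exonic/utr5/utr3 label).
#' @return data.frame per gene: gene_id, n_exonic_rep1, n_exonic_rep2,
#'   two_exonic_both, has_replicated_ase_snp, concordant_rep1,
#'   concordant_rep2, ase_strict (replicated ASE SNP + concordance in
#'   both), ase_lenient (replicated ASE SNP only), partial.
#' @export
flag_gene_criteria <- function(calls_rep1, calls_rep2, genes,
                               exonic_rep1 = NULL, exonic_rep2 = NULL) {
  partial <- is.null(calls_rep1) || is.null(calls_rep2)
  reps <- list(calls_rep1, calls_rep2)
  exonic <- list(exonic_rep1, exonic_rep2)
  for (r in 1:2) {
    if (is.null(reps[[r]])) next
    if (is.null(exonic[[r]]))
      exonic[[r]] <- rep(TRUE, nrow(reps[[r]]))
  }

  ase_sites <- lapply(reps, function(cc) {
    if (is.null(cc)) character(0)
    else paste(cc$contig, cc$pos)[cc$class == "ASE"]
  })
  replicated <- intersect(ase_sites[[1]], ase_sites[[2]])

  rows <- lapply(seq_len(nrow(genes)), function(g) {
    span <- genes[g, ]
    per_rep <- lapply(1:2, function(r) {
      cc <- reps[[r]]
      if (is.null(cc))
        return(list(n_exonic = NA_integer_, concordant = NA,
                    sites = character(0)))
      m <- cc$contig == span$contig & cc$pos >= span$start &
        cc$pos <= span$end & cc$class %in% c("ASE", "not_ASE")
      list(n_exonic = sum(m & exonic[[r]]),
           concordant = phase_concordance(cc$direction[m]),
           sites = paste(cc$contig, cc$pos)[m])
    })
    gene_sites <- unique(c(per_rep[[1]]$sites, per_rep[[2]]$sites))
    has_rep_ase <- length(intersect(gene_sites, replicated)) > 0L
    two_both <- if (partial) NA else
      per_rep[[1]]$n_exonic >= 2L && per_rep[[2]]$n_exonic >= 2L
    conc1 <- per_rep[[1]]$concordant
    conc2 <- per_rep[[2]]$concordant
    data.frame(gene_id = span$gene_id,
               n_exonic_rep1 = per_rep[[1]]$n_exonic,
               n_exonic_rep2 = per_rep[[2]]$n_exonic,
               two_exonic_both = two_both,
               has_replicated_ase_snp = has_rep_ase,
               concordant_rep1 = conc1, concordant_rep2 = conc2,
               ase_strict = has_rep_ase && isTRUE(conc1) && isTRUE(conc2),
               ase_lenient = has_rep_ase,
               partial = partial, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare ASE classifications between technical replicates
#'
#' For each minimum-depth threshold, restricts to sites testable (depth
#' at or above the threshold) and classified in both replicates and
#' tabulates the 2x2 ASE agreement, plus the Pearson correlation of
#' reference fractions. Raising the threshold trades testable sites for
#' classification reproducibility.
#'
#' @param calls_rep1,calls_rep2 classified call tables sharing a site
#'   universe (joined on contig+pos).
#' @param thresholds integer vector of minimum depths (default
#'   c(10, 50, 100)); values below 10 draw a warning (below the
#'   testability floor).
#' @return data.frame per threshold: threshold, n_testable_both,
#'   n_ase_both, n_ase_rep1_only, n_ase_rep2_only, n_not_ase_both,
#'   overlap_of_either (ASE-in-both / ASE-in-either; NA when no site is
#'   ASE in either), rf_correlation.
#' @export
compare_replicates <- function(calls_rep1, calls_rep2,
                               thresholds = c(10L, 50L, 100L)) {
  if (any(thresholds < 10))
    warning("depth threshold below 10 is below the testability floor")
  key1 <- paste(calls_rep1$contig, calls_rep1$pos)
  key2 <- paste(calls_rep2$contig, calls_rep2$pos)
  idx <- match(key1, key2)
  keep <- !is.na(idx)
  c1 <- calls_rep1[keep, , drop = FALSE]
  c2 <- calls_rep2[idx[keep], , drop = FALSE]

  out <- lapply(thresholds, function(t) {
    m <- c1$depth >= t & c2$depth >= t &
      c1$class %in% c("ASE", "not_ASE") &
      c2$class %in% c("ASE", "not_ASE")
    a1 <- c1$class[m] == "ASE"
    a2 <- c2$class[m] == "ASE"
    both <- sum(a1 & a2)
    only1 <- sum(a1 & !a2)
    only2 <- sum(!a1 & a2)
    either <- both + only1 + only2
    rfc <- if (sum(m) >= 3)
      suppressWarnings(cor(c1$ref_fraction[m], c2$ref_fraction[m],
                           use = "complete.obs"))
    else NA_real_
    data.frame(threshold = t, n_testable_both = sum(m),
               n_ase_both = both, n_ase_rep1_only = only1,
               n_ase_rep2_only = only2,
               n_not_ase_both = sum(!a1 & !a2),
               overlap_of_either = if (either > 0) both / either
               else NA_real_,
               rf_correlation = rfc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign testable SNPs to transcript isoforms
#'
#' A SNP is assigned to a transcript when it lies within one of that
#' transcript's exons; transcripts with no testable exonic SNP are
#' excluded. Per-transcript direction summaries expose isoform-specific
#' ASE: discordant imbalance directions between the SNP sets of two
#' isoforms of one gene suggest allele-specific isoform regulation.
#'
#' @param calls classified call table.
#' @param features per-transcript feature data.frame (exon rows used).
#' @return list with `assignments` (contig, pos, transcript_id, gene_id,
#'   direction, class) and `transcripts` (transcript_id, gene_id, n_snps,
#'   n_ase, n_toward_hapA, n_toward_hapB, discordant).
#' @export
map_snps_to_isoforms <- function(calls, features) {
  ex <- features[features$feature == "exon", , drop = FALSE]
  testable <- calls[calls$class %in% c("ASE", "not_ASE"), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ex))) {
    m <- testable$contig == ex$contig[i] &
      testable$pos >= ex$start[i] & testable$pos <= ex$end[i]
    if (!any(m)) next
    rows[[length(rows) + 1L]] <- data.frame(
      contig = testable$contig[m], pos = testable$pos[m],
      transcript_id = ex$transcript_id[i], gene_id = ex$gene_id[i],
      direction = testable$direction[m], class = testable$class[m],
      stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(contig = character(0), pos = integer(0),
               transcript_id = character(0), gene_id = character(0),
               direction = character(0), class = character(0),
               stringsAsFactors = FALSE)
  rownames(assignments) <- NULL

  tx <- lapply(split(assignments, assignments$transcript_id),
               function(d) {
    data.frame(transcript_id = d$transcript_id[1],
               gene_id = d$gene_id[1], n_snps = nrow(d),
               n_ase = sum(d$class == "ASE"),
               n_toward_hapA = sum(d$direction %in% "toward_hapA"),
               n_toward_hapB = sum(d$direction %in% "toward_hapB"),
               stringsAsFactors = FALSE)
  })
  transcripts <- if (length(tx)) do.call(rbind, tx) else
    data.frame(transcript_id = character(0), gene_id = character(0),
               n_snps = integer(0), n_ase = integer(0),
               n_toward_hapA = integer(0), n_toward_hapB = integer(0),
               stringsAsFactors = FALSE)
  transcripts$discordant <- transcripts$n_toward_hapA > 0L &
    transcripts$n_toward_hapB > 0L
  rownames(transcripts) <- NULL
  list(assignments = assignments, transcripts = transcripts)
}
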