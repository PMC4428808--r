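#' Annotate SNPs with proximal-variant evidence
#'
#' For every site, computes the genomic distance to the nearest un-phased
#' heterozygous indel (measured to the nearest edge of the indel's
#' reference-affected interval, not its VCF anchor base), the distance to
#' the nearest un-phased heterozygous SNP, and the number of proximal
#' heterozygous SNPs within `window` bp (excluding the site itself).
#' Un-phased variants are exactly those absent from the personalized
#' haplotype references and therefore able to cause alignment errors.
#'
#' @param sites data.frame with `contig`, `pos`.
#' @param unphased_snvs data.frame of un-phased het SNPs (`contig`,
#'   `pos`).
#' @param indels data.frame of un-phased indels with `contig`, `pos`
#'   (VCF anchor), `ref`, `alt`, `type` ("ins"/"del").
#' @param window window size in bp for the proximal-SNP count
#'   (default 100).
#' @param phased_snps optional data.frame of phased het SNPs; when given,
#'   these are included in the proximal-SNP count as well (by default the
#'   count covers un-phased SNPs only, the set the removal rule names).
#' @return data.frame with `indel_distance`, `snv_distance` (both `NA`
#'   when no such neighbour exists on the contig) and `proximal_count`.
#' @export
annotate_proximity <- function(sites, unphased_snvs, indels,
                               window = 100L, phased_snps = NULL) {
  n <- nrow(sites)
  indel_distance <- snv_distance <- rep(NA_real_, n)
  proximal_count <- integer(n)

  count_set <- unphased_snvs[, c("contig", "pos")]
  if (!is.null(phased_snps))
    count_set <- rbind(count_set, phased_snps[, c("contig", "pos")])

  for (ctg in unique(sites$contig)) {
    si <- which(sites$contig == ctg)
    p <- sites$pos[si]

    sp <- sort(unphased_snvs$pos[unphased_snvs$contig == ctg])
    if (length(sp))
      snv_distance[si] <- nearest_point_distance(p, sp)

    ind <- indels[indels$contig == ctg, , drop = FALSE]
    if (nrow(ind)) {
      iv <- indel_interval(ind)
      indel_distance[si] <- nearest_interval_distance(p, iv)
    }

    cs <- sort(count_set$pos[count_set$contig == ctg])
    if (length(cs)) {
      hi <- findInterval(p + window, cs)
      lo <- findInterval(p - window - 0.5, cs)
      self <- vapply(p, function(x) sum(cs == x), integer(1))
      proximal_count[si] <- hi - lo - self
    }
  }
  data.frame(indel_distance = indel_distance,
             snv_distance = snv_distance,
             proximal_count = proximal_count)
}

# reference-affected interval of a VCF-style indel: deletions affect the
# bases after the anchor; insertions sit between anchor and anchor+1
indel_interval <- function(ind) {
  del <- nchar(ind$ref) > nchar(ind$alt)
  start <- ifelse(del, ind$pos + 1L, ind$pos)
  end <- ifelse(del, ind$pos + nchar(ind$ref) - 1L, ind$pos + 1L)
  cbind(start, end)
}

nearest_point_distance <- function(p, sorted_pos) {
  i <- findInterval(p, sorted_pos)
  left <- ifelse(i >= 1L, p - sorted_pos[pmax(i, 1L)], Inf)
  right <- ifelse(i < length(sorted_pos),
                  sorted_pos[pmin(i + 1L, length(sorted_pos))] - p, Inf)
  d <- pmin(abs(left), abs(right))
  d
}

nearest_interval_distance <- function(p, iv) {
  vapply(p, function(x) {
    d <- ifelse(x < iv[, 1], iv[, 1] - x,
                ifelse(x > iv[, 2], x - iv[, 2], 0))
    min(d)
  }, numeric(1))
}

#' Alignability value at SNP positions
#'
#' Looks up each site's position in a precomputed alignability track
#' (BED-convention intervals: 0-based, half-open, values in `[0, 1]`,
#' 1 = uniquely alignable). Positions covered by no interval score 0.
#'
#' @param sites data.frame with `contig`, `pos` (1-based).
#' @param track data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and `value`.
#' @return numeric vector of alignability values.
#' @export
lookup_alignability <- function(sites, track) {
  if (any(track$value < 0 | track$value > 1))
    stop("alignability values must lie in [0, 1]")
  out <- numeric(nrow(sites))
  for (ctg in unique(sites$contig)) {
    tr <- track[track$contig == ctg, , drop = FALSE]
    si <- which(sites$contig == ctg)
    if (!nrow(tr)) next
    tr <- tr[order(tr$start), , drop = FALSE]
    overlap <- which(tr$start[-1] < tr$end[-nrow(tr)])
    if (length(overlap) &&
        any(tr$value[overlap] != tr$value[overlap + 1L]))
      stop("overlapping alignability intervals with conflicting values ",
           "on ", ctg)
    p0 <- sites$pos[si] - 1L  # 0-based position
    i <- findInterval(p0, tr$start)
    hit <- i >= 1L & p0 < tr$end[pmax(i, 1L)]
    out[si[hit]] <- tr$value[i[hit]]
  }
  out
}

#' Transcript-feature label for SNP positions
#'
#' Labels each site as coding_exonic, utr5, utr3, intronic or intergenic
#' from the union of all overlapping transcripts; sites whose overlapping
#' transcripts imply more than one distinct label are `"multiple"` (these
#' are discarded from single-feature analyses). A site inside a gene span
#' but within no transcript exon is intronic; outside all gene spans it
#' is intergenic.
#'
#' @param sites data.frame with `contig`, `pos`.
#' @param features per-transcript feature data.frame
#'   (see [generate_toy_reference()]; GTF-dialect feature names).
#' @param genes gene span data.frame.
#' @return character vector of labels.
#' @export
annotate_feature <- function(sites, features, genes) {
  vapply(seq_len(nrow(sites)), function(i) {
    ctg <- sites$contig[i]; p <- sites$pos[i]
    fo <- features[features$contig == ctg & features$start <= p &
                     features$end >= p, , drop = FALSE]
    labels <- character(0)
    tx_all <- unique(features$transcript_id[features$contig == ctg])
    for (tx in unique(fo$transcript_id)) {
      ft <- fo[fo$transcript_id == tx, , drop = FALSE]
      if ("CDS" %in% ft$feature) labels <- c(labels, "coding_exonic")
      else if ("five_prime_utr" %in% ft$feature) labels <- c(labels, "utr5")
      else if ("three_prime_utr" %in% ft$feature) labels <- c(labels, "utr3")
      else if ("exon" %in% ft$feature) labels <- c(labels, "coding_exonic")
    }
    # transcripts whose span covers the site without any exonic feature
    for (tx in setdiff(tx_all, unique(fo$transcript_id))) {
      ex <- features[features$transcript_id == tx &
                       features$feature == "exon", , drop = FALSE]
      if (nrow(ex) && min(ex$start) <= p && max(ex$end) >= p)
        labels <- c(labels, "intronic")
    }
    labels <- unique(labels)
    if (length(labels) > 1L) return("multiple")
    if (length(labels) == 1L) return(labels)
    in_gene <- any(genes$contig == ctg & genes$start <= p & genes$end >= p)
    if (in_gene) "intronic" else "intergenic"
  }, character(1))
}

#' Alignment-confounder removal rules for testable SNPs
#'
#' A SNP fails quality control when an un-phased indel lies within
#' `window` bp, when `snp_count_min` or more un-phased SNPs lie within
#' `window` bp, or when its alignability is below 1. "Within" is
#' inclusive (distance <= window).
#'
#' @param annotations data.frame with `indel_distance`, `proximal_count`
#'   and `alignability` columns (see [annotate_proximity()] and
#'   [lookup_alignability()]).
#' @param window proximity window in bp (default 100).
#' @param snp_count_min proximal un-phased SNP count that triggers
#'   removal (default 4).
#' @param perfect_alignability required alignability (default 1).
#' @return data.frame with `pass` flag and `reasons` (semicolon-joined
#'   subset of indel_within_100bp / four_plus_snps_within_100bp /
#'   imperfect_alignability; empty when passing).
#' @export
apply_qc_filters <- function(annotations, window = 100L,
                             snp_count_min = 4L,
                             perfect_alignability = 1) {
  fail_indel <- !is.na(annotations$indel_distance) &
    annotations$indel_distance <= window
  fail_snps <- annotations$proximal_count >= snp_count_min
  fail_align <- annotations$alignability < perfect_alignability
  reasons <- vapply(seq_len(nrow(annotations)), function(i) {
    r <- c(if (fail_indel[i]) "indel_within_100bp",
           if (fail_snps[i]) "four_plus_snps_within_100bp",
           if (fail_align[i]) "imperfect_alignability")
    paste(r, collapse = ";")
  }, character(1))
  data.frame(pass = !(fail_indel | fail_snps | fail_align),
             reasons = reasons, stringsAsFactors = FALSE)
}

#' ASE proportion within bins of a confounder covariate
#'
#' Diagnostic used to expose alignment confounders: classified SNPs are
#' binned by a covariate (distance to nearest indel or SNV, proximal-SNP
#' count, alignability, imputation R-squared, transcript feature) and the
#' proportion classified ASE in each bin is compared with the global ASE
#' proportion by an exact two-sided binomial test.
#'
#' @param calls classified calls (see [classify_snp_ase()]), restricted
#'   by the caller as desired.
#' @param key numeric or character covariate vector, one value per call
#'   row (`NA` rows are dropped).
#' @param breaks numeric bin edges for a numeric key (default the
#'   distance-style edges 0, 10, 100, 1000, 10000, Inf); ignored for a
#'   character/factor key.
#' @return data.frame with bin, n, n_ase, proportion, proportion_pct and
#'   p_value (`NA` for empty bins).
#' @export
binned_ase_proportion <- function(calls, key,
                                  breaks = c(0, 10, 100, 1000, 10000,
                                             Inf)) {
  use <- calls$class %in% c("ASE", "not_ASE") & !is.na(key)
  calls <- calls[use, , drop = FALSE]
  key <- key[use]
  if (!nrow(calls))
    return(data.frame(bin = character(0), n = integer(0),
                      n_ase = integer(0), proportion = numeric(0),
                      proportion_pct = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  bin <- if (is.numeric(key))
    cut(key, breaks = breaks, include.lowest = TRUE)
  else factor(key)
  global <- mean(calls$class == "ASE")
  out <- lapply(levels(bin), function(b) {
    idx <- which(bin == b)
    n <- length(idx)
    n_ase <- sum(calls$class[idx] == "ASE")
    pv <- if (n == 0L || global <= 0 || global >= 1) NA_real_
    else binom.test(n_ase, n, p = global)$p.value
    data.frame(bin = b, n = n, n_ase = n_ase,
               proportion = if (n) n_ase / n else NA_real_,
               proportion_pct = if (n) 100 * n_ase / n else NA_real_,
               p_value = pv, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
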