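#' Read-level filters for WGS genotype verification
#'
#' A WGS alignment contributes to heterozygosity verification only when
#' its aligned length (total CIGAR `M`) is at least 34 bp, its MD tag
#' encodes at most 4 substitution mismatches, its `SM` tag (single-end
#' mapping quality, BWA-specific) exceeds 10, and it is not a PCR
#' duplicate.
#'
#' @param cigar CIGAR string(s).
#' @param md MD tag value(s); `NA` when missing.
#' @param sm SM tag value(s); `NA` when missing.
#' @param is_duplicate PCR-duplicate flag(s).
#' @param missing_sm what to do when the SM tag is absent: `"fail"`
#'   (default; the tag is aligner-specific and its absence means the
#'   filter cannot be evaluated) or `"ignore"` (drop the SM condition).
#' @return logical vector: record passes the filters.
#' @examples
#' passes_read_filters("34M", "20A13", 11)   # TRUE (all boundaries)
#' passes_read_filters("33M", "33", 60)      # FALSE (too short)
#' @export
passes_read_filters <- function(cigar, md = NA, sm = NA,
                                is_duplicate = FALSE,
                                missing_sm = c("fail", "ignore")) {
  missing_sm <- match.arg(missing_sm)
  n <- max(length(cigar), length(md), length(sm), length(is_duplicate))
  cigar <- rep_len(cigar, n); md <- rep_len(md, n)
  sm <- rep_len(suppressWarnings(as.numeric(sm)), n)
  is_duplicate <- rep_len(is_duplicate, n)

  m_len <- cigar_m_width(cigar)
  mm <- md_mismatch_count(as.character(md))
  ok_len <- !is.na(m_len) & m_len >= 34L
  ok_md <- !is.na(mm) & mm <= 4L
  ok_sm <- if (missing_sm == "ignore") ifelse(is.na(sm), TRUE, sm > 10)
  else !is.na(sm) & sm > 10
  ok_len & ok_md & ok_sm & !is_duplicate
}

#' Heuristic heterozygous-SNP call from DNA allele counts
#'
#' A site is called heterozygous when the alternate allele count exceeds
#' 3 reads at total depth <= 12, exceeds 4 reads at depth 13-30, or makes
#' up at least 25% of reads at depth >= 31. Depth is the sum of reference
#' and alternate high-quality bases (third alleles excluded).
#'
#' @param ref_count,alt_count non-negative integer vectors.
#' @return data.frame with `call` ("het"/"not_het"), `rule_applied`
#'   (depth_le12 / depth_13_30 / depth_ge31) and `dna_reference_fraction`.
#' @examples
#' call_het_snp(8, 4)$call    # "het" (depth 12, alt > 3)
#' call_het_snp(26, 4)$call   # "not_het" (depth 30 needs alt > 4)
#' @export
call_het_snp <- function(ref_count, alt_count) {
  n <- max(length(ref_count), length(alt_count))
  ref_count <- rep_len(as.numeric(ref_count), n)
  alt_count <- rep_len(as.numeric(alt_count), n)
  if (any(ref_count < 0 | alt_count < 0))
    stop("allele counts must be non-negative")
  depth <- ref_count + alt_count
  if (any(depth < 1)) stop("total depth must be >= 1")
  het <- (depth <= 12 & alt_count > 3) |
    (depth >= 13 & depth <= 30 & alt_count > 4) |
    (depth >= 31 & alt_count >= 0.25 * depth)
  rule <- ifelse(depth <= 12, "depth_le12",
                 ifelse(depth <= 30, "depth_13_30", "depth_ge31"))
  data.frame(call = ifelse(het, "het", "not_het"), rule_applied = rule,
             dna_reference_fraction = ref_count / depth,
             stringsAsFactors = FALSE)
}

#' Heterozygosity verdict for a candidate indel
#'
#' An indel call is removed outright when it abuts or lies within a
#' homopolymer of seven or more bases, overlaps an annotated simple
#' repeat/satellite, or is 200 bp or longer. Otherwise it is heterozygous
#' when the supporting/informative read ratio lies in `[0.2, 0.7]`
#' (bounds inclusive; the bounds are configurable because the printed
#' rule does not state open or closed intervals).
#'
#' @param supporting_reads reads containing the indel.
#' @param informative_reads high-quality reads covering the locus
#'   (must be >= 1).
#' @param indel_length indel length in bases.
#' @param homopolymer7plus flag: contiguous with/embedded in a
#'   homopolymer run of >= 7 bases.
#' @param repeat_overlap flag: overlaps a RepeatMasker simple
#'   repeat/satellite interval.
#' @param bounds lower/upper heterozygosity ratio bounds.
#' @return character vector: `"het"`, `"not_het"` or `"removed"`.
#' @examples
#' call_het_indel(3, 10)   # "het" (ratio 0.3)
#' call_het_indel(8, 10)   # "not_het" (0.8)
#' @export
call_het_indel <- function(supporting_reads, informative_reads,
                           indel_length = 1L, homopolymer7plus = FALSE,
                           repeat_overlap = FALSE,
                           bounds = c(0.2, 0.7)) {
  n <- max(length(supporting_reads), length(informative_reads),
           length(indel_length), length(homopolymer7plus),
           length(repeat_overlap))
  supporting_reads <- rep_len(supporting_reads, n)
  informative_reads <- rep_len(informative_reads, n)
  len <- rep_len(indel_length, n)
  homopolymer7plus <- rep_len(homopolymer7plus, n)
  repeat_overlap <- rep_len(repeat_overlap, n)
  if (any(informative_reads < 1))
    stop("undefined heterozygosity ratio: informative_reads must be >= 1")
  if (any(supporting_reads > informative_reads))
    stop("supporting reads cannot exceed informative reads")
  ratio <- supporting_reads / informative_reads
  ifelse(homopolymer7plus | repeat_overlap | len >= 200L, "removed",
         ifelse(ratio >= bounds[1] & ratio <= bounds[2], "het",
                "not_het"))
}

#' Detect a homopolymer context around an indel interval
#'
#' TRUE when a maximal single-base run of at least `min_run` bases on the
#' reference contains or is immediately adjacent to the indel's
#' reference-affected interval.
#'
#' @param sequence reference contig sequence (character scalar).
#' @param start,end 1-based interval affected by the indel.
#' @param min_run minimum homopolymer length (default 7).
#' @return logical scalar.
#' @export
has_homopolymer_context <- function(sequence, start, end, min_run = 7L) {
  L <- nchar(sequence)
  win_s <- max(1L, start - min_run)
  win_e <- min(L, end + min_run)
  window <- substring(sequence, win_s, win_e)
  runs <- rle(strsplit(window, "")[[1]])
  run_end <- cumsum(runs$lengths) + win_s - 1L
  run_start <- run_end - runs$lengths + 1L
  long <- runs$lengths >= min_run
  if (!any(long)) return(FALSE)
  # adjacency: run touching [start-1, end+1]
  any(run_start[long] <= end + 1L & run_end[long] >= start - 1L)
}

#' Verify imputed heterozygous genotypes against WGS pileups
#'
#' Partitions imputed heterozygous variants into those whose WGS evidence
#' confirms heterozygosity (verified), those with confident non-het WGS
#' evidence (failed), and those with insufficient WGS depth (untestable).
#'
#' @param imputed data.frame of imputed het variants with columns
#'   `contig`, `pos`, `ref`, `alt`.
#' @param pileups data.frame of WGS pileup summaries with columns
#'   `contig`, `pos` and per-base counts `A`, `C`, `G`, `T` built from
#'   filter-passing reads (see [passes_read_filters()]).
#' @param min_depth minimum ref+alt WGS depth to attempt verification
#'   (default 8).
#' @return the input with an added `wgs_status` column in
#'   \{"verified", "failed", "untestable"\}; the three groups partition
#'   the input.
#' @export
verify_imputed_genotypes <- function(imputed, pileups, min_depth = 8L) {
  status <- rep("untestable", nrow(imputed))
  if (nrow(imputed)) {
    key <- paste(pileups$contig, pileups$pos)
    idx <- match(paste(imputed$contig, imputed$pos), key)
    for (i in seq_len(nrow(imputed))) {
      if (is.na(idx[i])) next
      p <- pileups[idx[i], , drop = FALSE]
      rc <- as.numeric(p[[imputed$ref[i]]])
      ac <- as.numeric(p[[imputed$alt[i]]])
      if (rc + ac < min_depth) next
      status[i] <- if (call_het_snp(rc, ac)$call == "het") "verified"
      else "failed"
    }
  }
  imputed$wgs_status <- status
  imputed
}
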