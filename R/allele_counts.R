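#' Count allele-resolved RNA-seq coverage at heterozygous SNPs
#'
#' Tallies, for each phased heterozygous SNP, the number of filtered
#' alignment records carrying the reference allele, the alternate allele,
#' or any other base. Mirrors a permissive pileup (no base-quality
#' threshold, no realignment-based quality adjustment): every mapped,
#' de-duplicated record overlapping the site contributes, and overlapping
#' mates are each counted. A site is testable when its total depth
#' reaches `min_depth` unique reads.
#'
#' Only ungapped records (single-`M` CIGARs) are counted; records with
#' gapped CIGARs are skipped with a warning.
#'
#' @param alignments filtered alignment data.frame
#'   (see [filter_alignments()]).
#' @param sites data.frame of heterozygous sites with columns `contig`,
#'   `pos`, `ref`, `alt` and `ref_on_hap` (`"A"` or `"B"`, the haplotype
#'   carrying the reference allele; `NA` allowed for un-phased sites,
#'   whose haplotype counts are then `NA`).
#' @param min_depth minimum unique-read depth for testability
#'   (default 10).
#' @param library_id library label carried into the output.
#' @param contig_lengths optional named integer vector; when supplied,
#'   a site outside any contig raises a coordinate error.
#' @return a site-counts data.frame: contig, pos, ref, alt, ref_count,
#'   alt_count, other_count, depth, ref_fraction (= ref/(ref+alt)),
#'   ref_on_hap, hap_a_count, hap_b_count, library_id, testable.
#' @export
pileup_counts <- function(alignments, sites, min_depth = 10L,
                          library_id = "lib1", contig_lengths = NULL) {
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  if (!is.null(contig_lengths) && nrow(sites)) {
    L <- unname(contig_lengths[sites$contig])
    bad <- is.na(L) | sites$pos < 1L | sites$pos > L
    if (any(bad))
      stop("site outside contig bounds: ", sites$contig[bad][1], ":",
           sites$pos[bad][1])
  }
  if (!"ref_on_hap" %in% names(sites)) sites$ref_on_hap <- NA_character_
  n <- nrow(sites)
  ref_count <- alt_count <- other_count <- integer(n)

  al <- alignments[alignments$mapped %in% TRUE, , drop = FALSE]
  if (nrow(al)) {
    simple <- cigar_is_simple(al$cigar)
    if (any(!simple)) {
      warning(sum(!simple), " gapped record(s) skipped in pileup")
      al <- al[simple, , drop = FALSE]
    }
  }
  if (nrow(al) && n) {
    width <- cigar_ref_width(al$cigar)
    for (ctg in unique(sites$contig)) {
      si <- which(sites$contig == ctg)
      ai <- which(al$contig == ctg)
      if (!length(ai)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(sites$pos[si], width = 1L),
        IRanges::IRanges(al$pos[ai], width = width[ai]))
      if (!length(hits)) next
      s_idx <- si[S4Vectors::queryHits(hits)]
      a_idx <- ai[S4Vectors::subjectHits(hits)]
      off <- sites$pos[s_idx] - al$pos[a_idx] + 1L
      base <- substring(al$seq[a_idx], off, off)
      is_ref <- base == sites$ref[s_idx]
      is_alt <- base == sites$alt[s_idx]
      ref_count <- ref_count +
        tabulate_at(s_idx[is_ref], n)
      alt_count <- alt_count +
        tabulate_at(s_idx[is_alt], n)
      other_count <- other_count +
        tabulate_at(s_idx[!is_ref & !is_alt], n)
    }
  }

  depth <- ref_count + alt_count + other_count
  informative <- ref_count + alt_count
  hap <- haplotype_counts(ref_count, alt_count, sites$ref_on_hap)
  data.frame(
    contig = sites$contig, pos = sites$pos,
    ref = sites$ref, alt = sites$alt,
    ref_count = ref_count, alt_count = alt_count,
    other_count = other_count, depth = depth,
    ref_fraction = ifelse(informative > 0, ref_count / informative,
                          NA_real_),
    ref_on_hap = sites$ref_on_hap,
    hap_a_count = hap$hap_a, hap_b_count = hap$hap_b,
    library_id = library_id, testable = depth >= min_depth,
    stringsAsFactors = FALSE)
}

tabulate_at <- function(idx, n) tabulate(idx, nbins = n)

#' Map reference/alternate counts onto haplotypes
#'
#' @param ref_count,alt_count allele counts.
#' @param ref_on_hap haplotype carrying the reference allele
#'   (`"A"`/`"B"`; `NA` yields `NA` haplotype counts).
#' @return data.frame with `hap_a` and `hap_b` counts
#'   (`hap_a + hap_b = ref_count + alt_count`).
#' @examples
#' haplotype_counts(30, 10, "A")  # hapA 30, hapB 10
#' haplotype_counts(30, 10, "B")  # hapA 10, hapB 30
#' @export
haplotype_counts <- function(ref_count, alt_count, ref_on_hap) {
  n <- max(length(ref_count), length(alt_count), length(ref_on_hap))
  ref_count <- rep_len(ref_count, n)
  alt_count <- rep_len(alt_count, n)
  ref_on_hap <- rep_len(as.character(ref_on_hap), n)
  if (any(!is.na(ref_on_hap) & !ref_on_hap %in% c("A", "B")))
    stop("ref_on_hap must be 'A', 'B' or NA")
  hap_a <- ifelse(is.na(ref_on_hap), NA_integer_,
                  ifelse(ref_on_hap == "A", ref_count, alt_count))
  hap_b <- ifelse(is.na(ref_on_hap), NA_integer_,
                  ifelse(ref_on_hap == "A", alt_count, ref_count))
  data.frame(hap_a = hap_a, hap_b = hap_b)
}

#' Gene-level RPKM from first-mate fragment starts
#'
#' Expression per gene is the number of R1 (first-in-pair) records whose
#' start position falls within the gene's annotated genomic boundaries,
#' scaled to reads per kilobase of gene span per million mapped R1
#' records.
#'
#' @param alignments filtered alignment data.frame.
#' @param genes gene span data.frame (gene_id, contig, start, end).
#' @return data.frame with gene_id, fragments, length_kb, rpkm.
#' @examples
#' genes <- data.frame(gene_id = "G", contig = "chr1",
#'                     start = 1, end = 1000)
#' @export
compute_rpkm <- function(alignments, genes) {
  r1 <- alignments[alignments$mate == 1L & alignments$mapped %in% TRUE, ,
                   drop = FALSE]
  total <- nrow(r1)
  if (total == 0L)
    stop("RPKM undefined: no mapped R1 records")
  frags <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    frags[i] <- sum(r1$contig == genes$contig[i] &
                      r1$pos >= genes$start[i] & r1$pos <= genes$end[i])
  }
  len_kb <- (genes$end - genes$start + 1) / 1000
  data.frame(gene_id = genes$gene_id, fragments = frags,
             length_kb = len_kb,
             rpkm = frags / (len_kb * total / 1e6),
             stringsAsFactors = FALSE)
}
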