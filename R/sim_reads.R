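#' Simulate allelically imbalanced paired reads with alignment triples
#'
#' Draws read pairs from the two haplotype genomes of a toy diploid.
#' Each pair is assigned to haplotype A with probability equal to its
#' gene's configured allelic ratio, placed ungapped within a single exon,
#' and given substitution sequencing errors at `base_error_rate`. For each
#' of the three reference spaces (maternal = haplotype A, paternal = B,
#' universal) the true edit distance of every mate is computed by direct
#' sequence comparison; a mate whose edit distance exceeds
#' `max_mismatches` is emitted as unmapped in that space, emulating an
#' aligner's mismatch tolerance (this is the mechanism behind reference
#' bias in universal-only alignment).
#'
#' @param reference output of [generate_toy_reference()].
#' @param variants output of [plant_phased_variants()] on the same
#'   reference.
#' @param config the [sim_config()] used.
#' @return a list with elements
#'   \describe{
#'     \item{reads}{data.frame with two rows (mates) per pair: qname,
#'       gene_id, hap, mate, contig, pos, strand, mapq, cigar, seq and the
#'       per-space edit distances nm_maternal / nm_paternal / nm_universal
#'       plus mapped flags.}
#'     \item{truth}{the truth table from [plant_phased_variants()].}
#'   }
#' @seealso [alignment_set()] to extract one space's alignment table.
#' @export
simulate_allelic_reads <- function(reference, variants, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)

  hapA <- as_seq_chars(build_haplotype_sequence(reference$genome,
                                                variants$phased,
                                                "A")$sequences)
  hapB <- as_seq_chars(build_haplotype_sequence(reference$genome,
                                                variants$phased,
                                                "B")$sequences)
  uni <- as_seq_chars(reference$genome)

  RL <- config$read_length
  feats <- reference$features
  out <- list()

  for (g in seq_len(nrow(reference$genes))) {
    gid <- reference$genes$gene_id[g]
    ctg <- reference$genes$contig[g]
    ex <- feats[feats$gene_id == gid & feats$feature == "exon" &
                  feats$transcript_id == paste0(gid, ".T1"), , drop = FALSE]
    w <- ex$end - ex$start + 1L
    usable <- w >= 2L * RL
    if (!any(usable)) next
    ex <- ex[usable, , drop = FALSE]; w <- w[usable]
    exonic_len <- sum(w)
    n_pairs <- max(1L, round(config$fragment_depth * exonic_len /
                               (2 * RL)))
    ratio <- 0.5
    if (!is.null(config$allelic_ratio_map) &&
        gid %in% names(config$allelic_ratio_map))
      ratio <- unname(config$allelic_ratio_map[[gid]])

    hap <- ifelse(runif(n_pairs) < ratio, "A", "B")
    ei <- sample.int(nrow(ex), n_pairs, replace = TRUE, prob = w)
    max_fl <- pmin(w[ei], 2L * RL + 100L)
    fl <- 2L * RL + floor(runif(n_pairs) * (max_fl - 2L * RL + 1L))
    start <- ex$start[ei] + floor(runif(n_pairs) * (w[ei] - fl + 1L))
    p1 <- start
    p2 <- start + fl - RL

    hseq <- ifelse(hap == "A", hapA[ctg], hapB[ctg])
    s1 <- substring(hseq, p1, p1 + RL - 1L)
    s2 <- substring(hseq, p2, p2 + RL - 1L)
    if (config$base_error_rate > 0) {
      s1 <- add_base_errors(s1, config$base_error_rate)
      s2 <- add_base_errors(s2, config$base_error_rate)
    }

    qname <- sprintf("%s_p%06d", gid, seq_len(n_pairs))
    pair <- data.frame(
      qname = rep(qname, each = 2L),
      gene_id = gid,
      hap = rep(hap, each = 2L),
      mate = rep(1:2, n_pairs),
      contig = ctg,
      pos = as.vector(rbind(p1, p2)),
      strand = rep(c("+", "-"), n_pairs),
      mapq = 60L,
      cigar = paste0(RL, "M"),
      seq = as.vector(rbind(s1, s2)),
      multimapped = FALSE,
      stringsAsFactors = FALSE)
    pair$mate_pos <- as.vector(rbind(p2, p1))

    for (space in c("maternal", "paternal", "universal")) {
      refc <- switch(space, maternal = hapA, paternal = hapB,
                     universal = uni)[ctg]
      refsub <- substring(refc, pair$pos, pair$pos + RL - 1L)
      pair[[paste0("nm_", space)]] <- str_mismatches(pair$seq, refsub)
      pair[[paste0("mapped_", space)]] <-
        pair[[paste0("nm_", space)]] <= config$max_mismatches
    }
    out[[gid]] <- pair
  }

  reads <- if (length(out)) do.call(rbind, out) else
    data.frame(qname = character(0))
  rownames(reads) <- NULL
  list(reads = reads, truth = variants$truth)
}

# substitution-only sequencing errors
add_base_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    L <- nchar(s)
    hit <- which(runif(L) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract one reference space's alignment table from simulated reads
#'
#' @param reads the `reads` element of [simulate_allelic_reads()].
#' @param origin `"maternal"`, `"paternal"` or `"universal"`.
#' @return an alignment data.frame in the standard column layout used by
#'   [merge_alignment_sets()]: qname, mate, mapped, contig, pos, strand,
#'   mapq, cigar, seq, nm, multimapped, mate_pos. `nm` is `NA` for
#'   unmapped mates.
#' @export
alignment_set <- function(reads, origin) {
  origin <- match.arg(origin, c("maternal", "paternal", "universal"))
  if (!nrow(reads))
    return(empty_alignments())
  mapped <- reads[[paste0("mapped_", origin)]]
  data.frame(
    qname = reads$qname, mate = reads$mate, mapped = mapped,
    contig = reads$contig, pos = reads$pos, strand = reads$strand,
    mapq = reads$mapq, cigar = ifelse(mapped, reads$cigar, "*"),
    seq = reads$seq,
    nm = ifelse(mapped, reads[[paste0("nm_", origin)]], NA_integer_),
    multimapped = reads$multimapped, mate_pos = reads$mate_pos,
    stringsAsFactors = FALSE)
}

empty_alignments <- function() {
  data.frame(qname = character(0), mate = integer(0), mapped = logical(0),
             contig = character(0), pos = integer(0), strand = character(0),
             mapq = integer(0), cigar = character(0), seq = character(0),
             nm = integer(0), multimapped = logical(0),
             mate_pos = integer(0), stringsAsFactors = FALSE)
}

#' Draw per-site allele counts directly from a binomial model
#'
#' Bypasses read simulation: at each site the reference-allele count is
#' drawn as Binomial(depth, true_rf). Useful for studying the sampling
#' behaviour of the SNP classifier at scale.
#'
#' @param true_rf true reference fraction in `[0, 1]` (scalar or length
#'   `n_sites`).
#' @param depth read depth per site (scalar or length `n_sites`).
#' @param n_sites number of sites.
#' @param seed integer RNG seed.
#' @param ref,alt ordered genotype to record (defaults "A"/"G").
#' @param library_id library label.
#' @return a site-counts data.frame as produced by [pileup_counts()]
#'   (reference allele assigned to haplotype A).
#' @examples
#' simulate_site_counts(0.5, 10, 5, seed = 1)
#' @export
simulate_site_counts <- function(true_rf, depth, n_sites, seed,
                                 ref = "A", alt = "G",
                                 library_id = "sim") {
  stopifnot(all(true_rf >= 0 & true_rf <= 1), all(depth >= 1),
            n_sites >= 1)
  set.seed(as.integer(seed))
  depth <- rep_len(as.integer(depth), n_sites)
  true_rf <- rep_len(true_rf, n_sites)
  ref_count <- rbinom(n_sites, depth, true_rf)
  alt_count <- depth - ref_count
  data.frame(
    contig = "sim", pos = seq_len(n_sites),
    ref = rep_len(ref, n_sites), alt = rep_len(alt, n_sites),
    ref_count = ref_count, alt_count = alt_count, other_count = 0L,
    depth = depth,
    ref_fraction = ifelse(depth > 0, ref_count / depth, NA_real_),
    ref_on_hap = "A",
    hap_a_count = ref_count, hap_b_count = alt_count,
    library_id = library_id, testable = depth >= 10L,
    stringsAsFactors = FALSE)
}
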