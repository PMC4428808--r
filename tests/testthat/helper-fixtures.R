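# shared builders for small in-code fixtures

small_config <- function(seed = 1L, ...) {
  defaults <- list(genome_length = 20000L, n_contigs = 1L, n_genes = 2L,
                   exons_per_gene = 3L, snp_rate = 0.005,
                   indel_count = 2L, het_fraction = 1,
                   unphased_fraction = 0.2, fragment_depth = 40,
                   base_error_rate = 0, seed = seed)
  do.call(sim_config, modifyList(defaults, list(...)))
}

# one candidate row for choose_alignment()
cand <- function(origin, m1 = TRUE, m2 = TRUE, nm1 = 0, nm2 = 0) {
  data.frame(origin = origin, mate1_mapped = m1, mate2_mapped = m2,
             nm1 = ifelse(m1, nm1, NA), nm2 = ifelse(m2, nm2, NA),
             stringsAsFactors = FALSE)
}

# minimal alignment table: one mapped ungapped pair
make_pair <- function(qname, contig = "chr1", pos1 = 100L, pos2 = 250L,
                      seq1 = NULL, seq2 = NULL, len = 100L, mapq = 60L,
                      nm = 0L, multimapped = FALSE) {
  if (is.null(seq1)) seq1 <- paste(rep("A", len), collapse = "")
  if (is.null(seq2)) seq2 <- paste(rep("A", len), collapse = "")
  data.frame(
    qname = qname, mate = 1:2, mapped = TRUE, contig = contig,
    pos = c(pos1, pos2), strand = c("+", "-"), mapq = mapq,
    cigar = paste0(c(nchar(seq1), nchar(seq2)), "M"),
    seq = c(seq1, seq2), nm = nm, multimapped = multimapped,
    mate_pos = c(pos2, pos1), stringsAsFactors = FALSE)
}

empty_set <- function() {
  alignment_set(data.frame(qname = character(0)), "universal")
}

# site-counts row with consistent derived columns
make_counts <- function(ref_count, alt_count, other_count = 0L,
                        ref = "A", alt = "G", ref_on_hap = "A",
                        pos = 1L, contig = "chr1", library_id = "lib1",
                        min_depth = 10L) {
  depth <- ref_count + alt_count + other_count
  hap <- haplotype_counts(ref_count, alt_count, ref_on_hap)
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             ref_count = ref_count, alt_count = alt_count,
             other_count = other_count, depth = depth,
             ref_fraction = ifelse(ref_count + alt_count > 0,
                                   ref_count / (ref_count + alt_count),
                                   NA_real_),
             ref_on_hap = ref_on_hap,
             hap_a_count = hap$hap_a, hap_b_count = hap$hap_b,
             library_id = library_id, testable = depth >= min_depth,
             stringsAsFactors = FALSE)
}

# independent enumeration oracle for the two-sided binomial
oracle_binom_two_sided <- function(k, n, p) {
  probs <- vapply(0:n, function(x) choose(n, x) * p^x * (1 - p)^(n - x),
                  numeric(1))
  ref <- probs[k + 1]
  sum(probs[probs <= ref * (1 + 1e-7)])
}

# independent statement of the alignment-selection rules, written as a
# literal transcription for oracle comparison
oracle_choose <- function(triple) {
  nmapped <- as.integer(triple$mate1_mapped) +
    as.integer(triple$mate2_mapped)
  if (max(nmapped) == 0) {
    return(if ("universal" %in% triple$origin) "universal"
           else triple$origin[1])
  }
  best <- triple[nmapped == max(nmapped), , drop = FALSE]
  nms <- ifelse(best$mate1_mapped, best$nm1, 0) +
    ifelse(best$mate2_mapped, best$nm2, 0)
  best <- best[nms == min(nms), , drop = FALSE]
  if (nrow(best) == 1) return(best$origin)
  if ("universal" %in% best$origin) return("universal")
  if ("maternal" %in% best$origin) return("maternal")
  "paternal"
}
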