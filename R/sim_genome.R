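#' Generate a toy reference genome with gene models
#'
#' Produces random contig sequences and non-overlapping gene models with
#' exon/intron structure, CDS and UTRs, so that every transcript feature
#' class (coding exonic, intronic, 5'UTR, 3'UTR, intergenic) is
#' representable. Genes with three or more exons also receive a second,
#' exon-skipping transcript so isoform-level assignment can be exercised.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements
#'   \describe{
#'     \item{genome}{`DNAStringSet` of contig sequences.}
#'     \item{genes}{data.frame of gene spans (gene_id, contig, start, end,
#'       strand).}
#'     \item{features}{data.frame of per-transcript features (contig,
#'       start, end, strand, feature, gene_id, transcript_id) with feature
#'       in exon/CDS/five_prime_utr/three_prime_utr.}
#'   }
#' @examples
#' ref <- generate_toy_reference(sim_config(genome_length = 10000,
#'                                          n_genes = 2, seed = 1))
#' @export
generate_toy_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  contig_len <- rep(config$genome_length %/% config$n_contigs,
                    config$n_contigs)
  contig_len[1] <- contig_len[1] + config$genome_length %% config$n_contigs
  contig_names <- paste0("chr", seq_len(config$n_contigs))

  seqs <- vapply(contig_len, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(setNames(seqs, contig_names))

  E <- config$exons_per_gene
  gene_span <- E * config$exon_length + (E - 1L) * config$intron_length
  flank <- 300L  # intergenic margin around genes and contig ends

  genes <- data.frame(gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  feats <- list()

  if (config$n_genes > 0L) {
    cursor <- setNames(rep(flank + 1L, config$n_contigs), contig_names)
    for (g in seq_len(config$n_genes)) {
      ctg <- contig_names[((g - 1L) %% config$n_contigs) + 1L]
      start <- cursor[[ctg]]
      end <- start + gene_span - 1L
      if (end > contig_len[match(ctg, contig_names)] - flank)
        stop("genome too short to host ", config$n_genes, " gene(s) of ",
             gene_span, " bp; increase 'genome_length'")
      cursor[[ctg]] <- end + flank + 1L
      strand <- if (g %% 2L == 1L) "+" else "-"
      gid <- sprintf("GENE%03d", g)

      exon_start <- start + (seq_len(E) - 1L) *
        (config$exon_length + config$intron_length)
      exon_end <- exon_start + config$exon_length - 1L
      genes <- rbind(genes, data.frame(
        gene_id = gid, contig = ctg, start = start, end = end,
        strand = strand, stringsAsFactors = FALSE))
      feats[[length(feats) + 1L]] <-
        gene_features(gid, paste0(gid, ".T1"), ctg, strand,
                      exon_start, exon_end, config)
      if (E >= 3L) {
        skip <- (E + 1L) %/% 2L
        feats[[length(feats) + 1L]] <-
          gene_features(gid, paste0(gid, ".T2"), ctg, strand,
                        exon_start[-skip], exon_end[-skip], config)
      }
    }
  }

  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), feature = character(0),
               gene_id = character(0), transcript_id = character(0),
               stringsAsFactors = FALSE)
  rownames(features) <- NULL
  list(genome = genome, genes = genes, features = features)
}

# feature rows (exon/CDS/UTR) for one transcript given its exon intervals
gene_features <- function(gene_id, tx_id, contig, strand,
                          exon_start, exon_end, config) {
  utr_len <- min(100L, config$exon_length %/% 4L)
  n <- length(exon_start)
  rows <- data.frame(contig = contig, start = exon_start, end = exon_end,
                     strand = strand, feature = "exon",
                     gene_id = gene_id, transcript_id = tx_id,
                     stringsAsFactors = FALSE)
  # first exon (in transcription order) starts with the 5'UTR, last ends
  # with the 3'UTR; everything else exonic is CDS
  first <- if (strand == "+") 1L else n
  last <- if (strand == "+") n else 1L
  utr5 <- if (strand == "+")
    c(exon_start[first], exon_start[first] + utr_len - 1L)
  else
    c(exon_end[first] - utr_len + 1L, exon_end[first])
  utr3 <- if (strand == "+")
    c(exon_end[last] - utr_len + 1L, exon_end[last])
  else
    c(exon_start[last], exon_start[last] + utr_len - 1L)

  cds <- lapply(seq_len(n), function(i) {
    s <- exon_start[i]; e <- exon_end[i]
    if (i == first) { if (strand == "+") s <- utr5[2] + 1L else e <- utr5[1] - 1L }
    if (i == last)  { if (strand == "+") e <- utr3[1] - 1L else s <- utr3[2] + 1L }
    if (s > e) NULL else c(s, e)
  })
  cds <- do.call(rbind, cds[!vapply(cds, is.null, logical(1))])

  rbind(rows,
        data.frame(contig = contig, start = cds[, 1], end = cds[, 2],
                   strand = strand, feature = "CDS",
                   gene_id = gene_id, transcript_id = tx_id,
                   stringsAsFactors = FALSE),
        data.frame(contig = contig,
                   start = c(utr5[1], utr3[1]), end = c(utr5[2], utr3[2]),
                   strand = strand,
                   feature = c("five_prime_utr", "three_prime_utr"),
                   gene_id = gene_id, transcript_id = tx_id,
                   stringsAsFactors = FALSE))
}
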