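# readers/writers for the standard formats the pipeline touches.
# FASTA via Biostrings, SAM/BAM reading via Rsamtools, GTF/bedGraph via
# rtracklayer, VCF reading via vcfR. The SAM/VCF/FASTQ writers format the
# synthetic fixtures' records directly.

#' Write an alignment table as SAM
#'
#' @param alignments alignment data.frame (standard layout; optional
#'   `origin` column becomes a `ZR:Z:` tag).
#' @param contig_lengths named integer vector for the `@SQ` header lines.
#' @param path output `.sam` path.
#' @return invisibly, the path.
#' @export
write_sam <- function(alignments, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  al <- alignments
  n <- nrow(al)
  if (n == 0L) { writeLines(hdr, path); return(invisible(path)) }

  flag <- rep(1L + 2L, n)                         # paired, proper
  flag <- flag + ifelse(al$mate == 1L, 64L, 128L)
  flag <- flag + ifelse(al$strand == "-", 16L, 0L)
  # FR pairs: the mate is on the opposite strand
  flag <- flag + ifelse(al$strand == "-", 0L, 32L)
  flag <- flag + ifelse(al$mapped, 0L, 4L)
  flag[!al$mapped] <- bitwAnd(flag[!al$mapped], bitwNot(2L))

  qual <- vapply(nchar(al$seq), function(L)
    paste(rep("I", L), collapse = ""), character(1))
  tags <- ifelse(al$mapped, sprintf("\tNM:i:%d", al$nm), "")
  if ("origin" %in% names(al))
    tags <- paste0(tags, sprintf("\tZR:Z:%s", al$origin))

  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s%s",
                 al$qname, flag,
                 ifelse(al$mapped, al$contig, "*"),
                 ifelse(al$mapped, al$pos, 0L),
                 ifelse(al$mapped, al$mapq, 0L),
                 ifelse(al$mapped, al$cigar, "*"),
                 ifelse(al$mapped, "=", "*"),
                 ifelse(al$mapped, al$mate_pos, 0L),
                 al$seq, qual, tags)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM or BAM file into the standard alignment table
#'
#' SAM text is converted with `Rsamtools::asBam()` and read back with
#' `scanBam()`, recovering the `NM` and `ZR` tags.
#'
#' @param path `.sam` or `.bam` file.
#' @return alignment data.frame (see [alignment_set()] for the layout),
#'   with an `origin` column when `ZR` tags are present.
#' @export
read_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "mpos"),
    tag = c("NM", "ZR"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- res$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  out <- data.frame(
    qname = res$qname,
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    mapped = mapped,
    contig = as.character(res$rname),
    pos = res$pos,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = res$mapq,
    cigar = ifelse(is.na(res$cigar), "*", res$cigar),
    seq = as.character(res$seq),
    nm = if (!is.null(res$tag$NM)) res$tag$NM else NA_integer_,
    multimapped = bitwAnd(flag, 256L) > 0L,
    mate_pos = res$mpos,
    stringsAsFactors = FALSE)
  out$nm[!out$mapped] <- NA_integer_
  if (!is.null(res$tag$ZR)) out$origin <- res$tag$ZR
  out
}

#' Write variants as a VCF file
#'
#' Heterozygous phased variants get a phased genotype `a|b` whose first
#' allele is the one on haplotype A; un-phased variants get `a/b`.
#'
#' @param variants variant data.frame (`contig`, `pos`, `ref`, `alt`;
#'   optional `zygosity`, `hap_a`, `hap_b`, `r_squared`, `source`).
#' @param path output `.vcf` path.
#' @param sample_name sample column name.
#' @return invisibly, the path.
#' @export
write_vcf <- function(variants, path, sample_name = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation R-squared\">",
           "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Variant source\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_name))
  if (!nrow(variants)) { writeLines(hdr, path); return(invisible(path)) }
  v <- variants[order(variants$contig, variants$pos), , drop = FALSE]
  zyg <- if ("zygosity" %in% names(v)) v$zygosity else "het"
  phased <- "hap_a" %in% names(v) && !all(is.na(v$hap_a))
  gt <- if (phased) {
    a <- ifelse(v$hap_a == v$ref, "0", "1")
    b <- ifelse(v$hap_b == v$ref, "0", "1")
    ifelse(is.na(v$hap_a), "0/1", paste0(a, "|", b))
  } else ifelse(zyg == "hom_alt", "1/1", "0/1")
  info <- rep(".", nrow(v))
  if ("r_squared" %in% names(v))
    info <- sprintf("R2=%s", v$r_squared)
  if ("source" %in% names(v))
    info <- paste0(info, ";SRC=", v$source)
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tGT\t%s",
                 v$contig, v$pos, v$ref, v$alt, info, gt)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a VCF of small variants into the package's variant table
#'
#' Uses `vcfR`; phased heterozygous genotypes (`a|b`) are interpreted
#' with the first allele on haplotype A.
#'
#' @param path `.vcf` file.
#' @return data.frame with contig, pos, ref, alt, zygosity, hap_a,
#'   hap_b, r_squared, source, class ("snp"/"indel").
#' @export
read_vcf_variants <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  gt <- if (ncol(v@gt) >= 2L)
    vcfR::extract.gt(v, element = "GT")[, 1] else rep("0/1", n)
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, "R2")))
  src <- vcfR::extract.info(v, "SRC")
  ref <- fix$REF; alt <- fix$ALT
  phased <- grepl("\\|", gt)
  alleles <- strsplit(gsub("\\|", "/", gt), "/")
  a1 <- vapply(alleles, `[`, character(1), 1L)
  a2 <- vapply(alleles, function(x) x[min(2L, length(x))], character(1))
  zyg <- ifelse(a1 == a2 & a1 == "1", "hom_alt",
                ifelse(a1 == a2, "hom_ref", "het"))
  pick <- function(code) ifelse(code == "0", ref, alt)
  data.frame(
    contig = fix$CHROM, pos = as.integer(fix$POS), ref = ref, alt = alt,
    zygosity = zyg,
    hap_a = ifelse(phased, pick(a1), NA_character_),
    hap_b = ifelse(phased, pick(a2), NA_character_),
    r_squared = r2,
    source = if (all(is.na(src))) NA_character_ else src,
    class = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "snp", "indel"),
    stringsAsFactors = FALSE)
}

#' Write gene models as GTF (Ensembl dialect)
#'
#' @param features feature data.frame (see [generate_toy_reference()]).
#' @param path output `.gtf` path.
#' @return invisibly, the path.
#' @export
write_gtf <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- features$feature
  S4Vectors::mcols(gr)$source <- "asequant"
  S4Vectors::mcols(gr)$gene_id <- features$gene_id
  S4Vectors::mcols(gr)$transcript_id <- features$transcript_id
  S4Vectors::mcols(gr)$phase <- ifelse(features$feature == "CDS", 0L,
                                       NA_integer_)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF annotation into the package's feature/gene tables
#'
#' @param path `.gtf` file.
#' @return list with `features` (exon/CDS/UTR rows) and `genes` (gene
#'   spans, derived from the union of each gene's features when no gene
#'   rows are present).
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(S4Vectors::mcols(gr)$type),
    gene_id = S4Vectors::mcols(gr)$gene_id,
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    stringsAsFactors = FALSE)
  feats <- df[df$feature %in% c("exon", "CDS", "five_prime_utr",
                                "three_prime_utr"), , drop = FALSE]
  genes <- do.call(rbind, lapply(split(df, df$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], contig = d$contig[1],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(feats) <- rownames(genes) <- NULL
  list(features = feats, genes = genes)
}

#' Write an alignability track as bedGraph
#'
#' @param track data.frame with contig, start, end (0-based half-open)
#'   and value.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_alignability <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", track$contig,
                     as.integer(track$start), as.integer(track$end),
                     track$value), path)
  invisible(path)
}

#' Read an alignability bedGraph track
#'
#' @param path bedGraph file.
#' @return data.frame with contig, start, end (0-based half-open),
#'   value.
#' @export
read_alignability <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             value = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE)
}

#' Write simulated read pairs as FASTQ
#'
#' Mate-2 sequences are reverse-complemented into read orientation.
#'
#' @param reads the `reads` element of [simulate_allelic_reads()].
#' @param r1_path,r2_path output paths.
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  for (m in 1:2) {
    r <- reads[reads$mate == m, , drop = FALSE]
    s <- if (m == 2L) reverse_complement(r$seq) else r$seq
    qual <- vapply(nchar(s), function(L)
      paste(rep("I", L), collapse = ""), character(1))
    writeLines(as.vector(rbind(paste0("@", r$qname, "/", m), s, "+",
                               qual)),
               if (m == 1L) r1_path else r2_path)
  }
  invisible(c(r1_path, r2_path))
}

#' Write a complete synthetic fixture directory
#'
#' Materializes one simulated diploid data set as the standard file
#' formats the pipeline consumes: reference FASTA, haplotype FASTAs,
#' phased and un-phased VCFs, FASTQ pairs, three SAM alignment sets,
#' GTF annotation, a perfect-alignability bedGraph and the truth table.
#'
#' @param reference output of [generate_toy_reference()].
#' @param variants output of [plant_phased_variants()].
#' @param sim output of [simulate_allelic_reads()].
#' @param dir output directory (created).
#' @param alignability optional track data.frame; default covers every
#'   contig with value 1.
#' @return named list of file paths.
#' @export
write_sim_fixture <- function(reference, variants, sim, dir,
                              alignability = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  contig_lengths <- setNames(Biostrings::width(reference$genome),
                             names(reference$genome))

  Biostrings::writeXStringSet(reference$genome, p("reference.fa"),
                              width = 60L)
  write_haplotype_fastas(reference$genome, variants$phased,
                         p("reference"))
  write_vcf(variants$phased, p("phased.vcf"))
  unph <- rbind(
    variants$unphased_snvs[, c("contig", "pos", "ref", "alt")],
    variants$indels[, c("contig", "pos", "ref", "alt")])
  write_vcf(unph, p("unphased.vcf"))
  write_fastq(sim$reads, p("reads_R1.fastq"), p("reads_R2.fastq"))
  for (o in c("maternal", "paternal", "universal"))
    write_sam(alignment_set(sim$reads, o), contig_lengths,
              p(paste0(o, ".sam")))
  write_gtf(reference$features, p("annotation.gtf"))
  if (is.null(alignability))
    alignability <- data.frame(contig = names(contig_lengths),
                               start = 0L,
                               end = unname(contig_lengths),
                               value = 1)
  write_alignability(alignability, p("alignability.bedgraph"))
  write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  list(reference = p("reference.fa"),
       hap_a = p("reference_hapA.fa"), hap_b = p("reference_hapB.fa"),
       phased_vcf = p("phased.vcf"), unphased_vcf = p("unphased.vcf"),
       fastq_r1 = p("reads_R1.fastq"), fastq_r2 = p("reads_R2.fastq"),
       maternal_sam = p("maternal.sam"),
       paternal_sam = p("paternal.sam"),
       universal_sam = p("universal.sam"),
       gtf = p("annotation.gtf"),
       alignability = p("alignability.bedgraph"),
       truth = p("truth.tsv"))
}
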