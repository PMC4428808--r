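#' Build a personalized haplotype genome sequence
#'
#' Substitutes phased SNP alleles into the universal reference to produce
#' one haplotype's genome. Heterozygous SNPs contribute the allele carried
#' by the requested haplotype; homozygous-alternate SNPs are substituted
#' into both haplotypes. Only single-base substitutions are accepted, so
#' every contig keeps its reference length and all coordinates remain
#' comparable across the maternal, paternal and universal spaces.
#' Haplotype A is labeled "maternal" and B "paternal", purely as labels.
#'
#' @param reference a `DNAStringSet` or named character vector of contig
#'   sequences.
#' @param variants data.frame of phased variants with columns `contig`,
#'   `pos` (1-based), `ref`, `alt`, `zygosity` ("het"/"hom_alt"), `hap_a`,
#'   `hap_b`, and optionally `class` ("snp"). Indels are rejected.
#' @param haplotype `"A"` or `"B"` (aliases `"maternal"`/`"paternal"`).
#' @return a list of class `haplotype_genome` with elements `haplotype`,
#'   `sequences` (`DNAStringSet`) and `n_substitutions`.
#' @examples
#' ref <- c(chr1 = "ACGT")
#' v <- data.frame(contig = "chr1", pos = 2, ref = "C", alt = "T",
#'                 zygosity = "het", hap_a = "C", hap_b = "T")
#' build_haplotype_sequence(ref, v, "B")
#' @export
build_haplotype_sequence <- function(reference, variants, haplotype) {
  haplotype <- normalize_haplotype(haplotype)
  seqs <- as_seq_chars(reference)

  if (nrow(variants)) {
    if ("class" %in% names(variants) && any(variants$class != "snp"))
      stop("indels cannot be substituted into a haplotype genome; ",
           "personalization is SNP-only")
    if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L))
      stop("indels cannot be substituted into a haplotype genome; ",
           "personalization is SNP-only")
    key <- paste(variants$contig, variants$pos)
    if (anyDuplicated(key))
      stop("overlapping/multi-allelic variant records at ",
           key[duplicated(key)][1], "; resolve before personalization")
    bad_ctg <- setdiff(unique(variants$contig), names(seqs))
    if (length(bad_ctg))
      stop("variant contig not in reference: ", bad_ctg[1])
  }

  n_sub <- 0L
  out <- seqs
  for (ctg in unique(variants$contig)) {
    v <- variants[variants$contig == ctg, , drop = FALSE]
    L <- nchar(seqs[[ctg]])
    if (any(v$pos < 1L | v$pos > L))
      stop("variant position outside contig ", ctg)
    obs <- substring(seqs[[ctg]], v$pos, v$pos)
    if (any(obs != v$ref))
      stop("reference mismatch at ", ctg, ":", v$pos[obs != v$ref][1],
           ": VCF says ", v$ref[obs != v$ref][1], ", reference has ",
           obs[obs != v$ref][1])
    allele <- if (haplotype == "A") v$hap_a else v$hap_b
    if (any(is.na(allele)))
      stop("un-phased variant passed to build_haplotype_sequence")
    change <- allele != v$ref
    if (any(change)) {
      s <- Biostrings::DNAString(seqs[[ctg]])
      s <- Biostrings::replaceLetterAt(s, v$pos[change], allele[change])
      out[[ctg]] <- as.character(s)
      n_sub <- n_sub + sum(change)
    }
  }
  structure(list(haplotype = haplotype,
                 sequences = Biostrings::DNAStringSet(out),
                 n_substitutions = n_sub),
            class = "haplotype_genome")
}

normalize_haplotype <- function(haplotype) {
  h <- switch(tolower(as.character(haplotype)[1]),
              a = "A", maternal = "A",
              b = "B", paternal = "B",
              stop("haplotype must be 'A'/'maternal' or 'B'/'paternal'"))
  h
}

#' @export
print.haplotype_genome <- function(x, ...) {
  cat("haplotype", x$haplotype, "genome:", length(x$sequences),
      "contig(s),", x$n_substitutions, "substitution(s)\n")
  invisible(x)
}

#' Write maternal/paternal haplotype FASTA files
#'
#' @param reference `DNAStringSet` or named character vector.
#' @param variants phased variant data.frame (see
#'   [build_haplotype_sequence()]).
#' @param out_prefix path prefix; files `<prefix>_hapA.fa` and
#'   `<prefix>_hapB.fa` are written (60-column, uppercase).
#' @return invisibly, the two file paths.
#' @export
write_haplotype_fastas <- function(reference, variants, out_prefix) {
  paths <- character(2)
  for (i in 1:2) {
    h <- c("A", "B")[i]
    hg <- build_haplotype_sequence(reference, variants, h)
    paths[i] <- paste0(out_prefix, "_hap", h, ".fa")
    Biostrings::writeXStringSet(hg$sequences, paths[i], width = 60L)
  }
  invisible(paths)
}
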