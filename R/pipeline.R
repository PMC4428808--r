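#' Run the full ASE quantification workflow
#'
#' Orchestrates the recommended workflow on files: personalize (haplotype
#' FASTAs from phased SNPs) -> merge (three-way alignment selection) ->
#' filter (duplicates, multi-mappers, MAPQ, chrM) -> count (allele
#' pileup at phased het SNPs) -> classify (ordered-genotype medians +
#' two-sided binomial + effect size) -> qc (proximal variants,
#' alignability, features) -> gene-ase (haplotype-summed aggregation).
#' Every stage's table is written as TSV, together with a JSON manifest
#' of all result-affecting parameters and a per-stage tally log. Given
#' fixed inputs the outputs are byte-identical across reruns.
#'
#' @param config a named list or path to a YAML file with entries:
#'   paths `reference_fasta`, `phased_vcf`, `unphased_vcf`,
#'   `maternal_sam`, `paternal_sam`, `universal_sam`, `gtf`,
#'   `alignability_bed`, `out_dir`; optional thresholds `min_depth`
#'   (10), `delta` (0.15), `alpha` (0.05), `proximity_window` (100),
#'   `proximal_snp_min` (4), `min_mapq` (9), `mito_name` ("chrM"),
#'   `binomial_method` ("min_likelihood"), `library_id` ("lib1").
#'   An optional `wgs_pileup_tsv` (columns contig, pos, A, C, G, T)
#'   enables the WGS-verification stage: only heterozygous SNPs whose
#'   DNA counts pass the heuristic het rules are tested (minimum DNA
#'   depth `wgs_min_depth`, default 8).
#'   CLI-style overrides can be layered by the caller before invoking.
#' @return invisibly, a result bundle: merged/filtered alignments,
#'   counts, calls, qc, gene table, isoform assignments, rpkm, tallies
#'   and output paths.
#' @export
run_ase_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(min_depth = 10L, delta = 0.15, alpha = 0.05,
                   proximity_window = 100L, proximal_snp_min = 4L,
                   min_mapq = 9L, mito_name = "chrM",
                   binomial_method = "min_likelihood",
                   library_id = "lib1")
  config <- modifyList(defaults, config)

  stage <- function(name, keys) {
    for (k in keys) {
      p <- config[[k]]
      if (is.null(p) || !file.exists(p))
        stop("stage '", name, "' prerequisite missing: ", k,
             if (!is.null(p)) paste0(" (", p, ")") else "",
             call. = FALSE)
    }
  }
  need <- function(key) {
    if (is.null(config[[key]]))
      stop("config entry '", key, "' is required", call. = FALSE)
    config[[key]]
  }

  out_dir <- need("out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  # --- inputs ---------------------------------------------------------
  stage("personalize", c("reference_fasta", "phased_vcf"))
  reference <- Biostrings::readDNAStringSet(need("reference_fasta"))
  names(reference) <- sub("\\s.*$", "", names(reference))
  phased <- read_vcf_variants(need("phased_vcf"))
  phased <- phased[phased$class == "snp", , drop = FALSE]
  note("personalize: ", nrow(phased), " phased SNP(s)")

  hap_paths <- write_haplotype_fastas(
    reference, phased, file.path(out_dir, "personalized"))

  stage("merge", c("maternal_sam", "paternal_sam", "universal_sam"))
  merged <- merge_alignment_sets(read_sam(need("maternal_sam")),
                                 read_sam(need("paternal_sam")),
                                 read_sam(need("universal_sam")))
  note("merge: ", nrow(merged$alignments), " record(s) from ",
       nrow(merged$decisions), " read pair(s)")

  flt <- filter_alignments(merged$alignments,
                           min_mapq = config$min_mapq,
                           mito_name = config$mito_name)
  note("filter: removed ",
       paste(names(flt$tally), flt$tally, sep = "=", collapse = ", "))

  # --- optional WGS verification --------------------------------------
  het <- phased[phased$zygosity == "het", , drop = FALSE]
  if (!is.null(config$wgs_pileup_tsv)) {
    stage("verify", "wgs_pileup_tsv")
    pile <- read.table(config$wgs_pileup_tsv, header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
    ver <- verify_imputed_genotypes(het, pile,
                                    min_depth = config$wgs_min_depth %||%
                                      8L)
    note("verify: ", sum(ver$wgs_status == "verified"), " verified, ",
         sum(ver$wgs_status == "failed"), " failed, ",
         sum(ver$wgs_status == "untestable"), " untestable")
    het <- het[ver$wgs_status == "verified", , drop = FALSE]
  }

  # --- allele counts --------------------------------------------------
  het$ref_on_hap <- ifelse(het$hap_a == het$ref, "A", "B")
  counts <- pileup_counts(
    flt$alignments, het, min_depth = config$min_depth,
    library_id = config$library_id,
    contig_lengths = setNames(Biostrings::width(reference),
                              names(reference)))
  note("count: ", sum(counts$testable), " of ", nrow(counts),
       " het SNP(s) testable at depth >= ", config$min_depth)

  medians <- compute_bin_medians(counts)
  calls <- classify_snp_ase(counts, medians,
                            delta_threshold = config$delta,
                            alpha = config$alpha,
                            min_depth = config$min_depth,
                            method = config$binomial_method)
  note("classify: ", sum(calls$class == "ASE"), " ASE SNP(s)")

  # --- QC -------------------------------------------------------------
  stage("qc", c("unphased_vcf", "alignability_bed"))
  unphased <- read_vcf_variants(need("unphased_vcf"))
  track <- read_alignability(need("alignability_bed"))
  stage("gene-ase", "gtf")
  anno <- read_gtf(need("gtf"))

  prox <- annotate_proximity(
    calls, unphased[unphased$class == "snp", , drop = FALSE],
    unphased[unphased$class == "indel", , drop = FALSE],
    window = config$proximity_window)
  prox$alignability <- lookup_alignability(calls, track)
  prox$feature <- annotate_feature(calls, anno$features, anno$genes)
  qc <- apply_qc_filters(prox, window = config$proximity_window,
                         snp_count_min = config$proximal_snp_min)
  note("qc: ", sum(!qc$pass & calls$testable),
       " testable SNP(s) removed")

  # --- locus level ----------------------------------------------------
  gene_ase <- aggregate_gene_ase(calls, anno$genes, qc = qc)
  isoforms <- map_snps_to_isoforms(calls[qc$pass, , drop = FALSE],
                                   anno$features)
  rpkm <- compute_rpkm(flt$alignments, anno$genes)
  note("gene-ase: ", nrow(gene_ase), " gene(s) with member SNPs")

  # --- outputs --------------------------------------------------------
  tsv <- function(x, f) {
    path <- file.path(out_dir, f)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- list(
    hap_a = hap_paths[1], hap_b = hap_paths[2],
    site_counts = tsv(counts, "site_counts.tsv"),
    snp_calls = tsv(cbind(calls, prox, qc), "snp_calls.tsv"),
    gene_ase = tsv(gene_ase, "gene_ase.tsv"),
    isoforms = tsv(isoforms$transcripts, "isoform_ase.tsv"),
    rpkm = tsv(rpkm, "rpkm.tsv"))

  manifest <- config[c("min_depth", "delta", "alpha",
                       "proximity_window", "proximal_snp_min",
                       "min_mapq", "mito_name", "binomial_method",
                       "library_id")]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))

  invisible(list(alignments = flt$alignments, filter_tally = flt$tally,
                 decisions = merged$decisions, counts = counts,
                 medians = medians, calls = calls, proximity = prox,
                 qc = qc, gene_ase = gene_ase, isoforms = isoforms,
                 rpkm = rpkm, paths = paths, log = log_lines))
}
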