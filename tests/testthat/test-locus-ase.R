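gene1 <- data.frame(gene_id = "G1", contig = "chr1", start = 1,
                    end = 10000)

calls_from_counts <- function(counts) {
  m <- structure(list(bins = data.frame(library_id = counts$library_id[1],
                                        genotype = "A>G",
                                        median_rf = 0.5,
                                        n = nrow(counts)),
                      fallback = data.frame(
                        library_id = counts$library_id[1],
                        median_rf = 0.5)),
                 class = "bin_median_table")
  classify_snp_ase(counts, m)
}

test_that("gene aggregation sums haplotype counts and tests them at 0.5", {
  counts <- rbind(make_counts(30, 10, pos = 100),
                  make_counts(25, 15, pos = 200))
  res <- aggregate_gene_ase(calls_from_counts(counts), gene1)
  expect_equal(res$hap_a_sum, 55)
  expect_equal(res$hap_b_sum, 25)
  expect_equal(res$p_value, binomial_two_sided(25, 80, 0.5))
  expect_equal(res$n_testable_snps, 2L)
  # perfectly balanced sums give p = 1
  bal <- rbind(make_counts(20, 20, pos = 100),
               make_counts(20, 20, pos = 200))
  expect_equal(aggregate_gene_ase(calls_from_counts(bal), gene1)$p_value,
               1)
  # a single-SNP gene reduces to that SNP's binomial at 0.5
  single <- make_counts(18, 6, pos = 100)
  expect_equal(
    aggregate_gene_ase(calls_from_counts(single), gene1)$p_value,
    binomial_two_sided(18, 24, 0.5))
  # sum conservation against member counts
  expect_equal(res$hap_a_sum + res$hap_b_sum,
               sum(counts$hap_a_count + counts$hap_b_count))
})

test_that("gene p-value is non-increasing in haplotype imbalance at fixed depth", {
  p_at <- function(a) {
    cc <- calls_from_counts(make_counts(a, 60 - a, pos = 100))
    aggregate_gene_ase(cc, gene1)$p_value
  }
  pv <- vapply(30:55, p_at, numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("phase concordance ignores balanced members and single SNPs", {
  expect_true(phase_concordance(c("toward_hapA", "toward_hapA")))
  expect_false(phase_concordance(c("toward_hapA", "toward_hapB")))
  expect_true(phase_concordance("toward_hapB"))
  expect_true(phase_concordance(c("toward_hapA", "balanced",
                                  "toward_hapA")))
  expect_true(phase_concordance(character(0)))
})

test_that("replicate flags identify replicated ASE SNPs and exonic support", {
  c1 <- calls_from_counts(rbind(make_counts(19, 1, pos = 100),
                                make_counts(10, 10, pos = 200)))
  c2 <- calls_from_counts(rbind(make_counts(18, 2, pos = 100),
                                make_counts(11, 9, pos = 200)))
  flags <- flag_gene_criteria(c1, c2, gene1)
  expect_true(flags$has_replicated_ase_snp)
  expect_true(flags$two_exonic_both)
  expect_true(flags$concordant_rep1)
  expect_true(flags$ase_strict)
  expect_false(flags$partial)

  # one replicate with a single testable exonic SNP fails the 2-SNP rule
  flags2 <- flag_gene_criteria(c1, c2[1, ], gene1)
  expect_false(flags2$two_exonic_both)
  # replicated ASE requires the same site ASE in both
  c3 <- calls_from_counts(rbind(make_counts(10, 10, pos = 100),
                                make_counts(19, 1, pos = 200)))
  expect_false(flag_gene_criteria(c1, c3, gene1)$has_replicated_ase_snp)
  # missing replicate -> partial
  expect_true(flag_gene_criteria(c1, NULL, gene1)$partial)
})

test_that("replicate comparison partitions the shared testable set", {
  mk <- function(ase_pos, depths, positions = c(100, 200, 300, 400)) {
    counts <- do.call(rbind, lapply(seq_along(positions), function(i) {
      if (positions[i] %in% ase_pos)
        make_counts(round(depths[i] * 0.95),
                    depths[i] - round(depths[i] * 0.95),
                    pos = positions[i])
      else make_counts(ceiling(depths[i] / 2), floor(depths[i] / 2),
                       pos = positions[i])
    }))
    calls_from_counts(counts)
  }
  r1 <- mk(c(100, 200), c(40, 40, 40, 40))
  r2 <- mk(c(200, 300), c(40, 40, 40, 40))
  cmp <- compare_replicates(r1, r2, thresholds = c(10, 50))
  expect_equal(cmp$n_testable_both, c(4L, 0L))
  expect_equal(cmp$n_ase_both[1], 1L)
  expect_equal(cmp$n_ase_rep1_only[1], 1L)
  expect_equal(cmp$n_ase_rep2_only[1], 1L)
  expect_equal(cmp$n_not_ase_both[1], 1L)
  expect_equal(cmp$overlap_of_either[1], 1 / 3)
  # identical callsets have no rep-only calls
  same <- compare_replicates(r1, r1, thresholds = 10)
  expect_equal(same$n_ase_rep1_only, 0L)
  expect_equal(same$n_ase_rep2_only, 0L)
  expect_equal(same$overlap_of_either, 1)
  expect_warning(compare_replicates(r1, r2, thresholds = 5), "floor")
})

test_that("planted imbalanced gene ranks first with recovered ratio", {
  n_genes <- 8
  cfg <- small_config(genome_length = 60000, n_genes = n_genes,
                      fragment_depth = 80, unphased_fraction = 0,
                      snp_rate = 0.004, base_error_rate = 0,
                      allelic_ratio_map = c(GENE003 = 0.9), seed = 5)
  ref <- generate_toy_reference(cfg)
  v <- plant_phased_variants(ref, cfg)
  sim <- simulate_allelic_reads(ref, v, cfg)
  merged <- merge_alignment_sets(alignment_set(sim$reads, "maternal"),
                                 alignment_set(sim$reads, "paternal"),
                                 alignment_set(sim$reads, "universal"))
  flt <- filter_alignments(merged$alignments)
  sites <- v$truth[v$truth$phased, ]
  counts <- pileup_counts(flt$alignments, sites)
  calls <- classify_snp_ase(counts, compute_bin_medians(counts))
  res <- aggregate_gene_ase(calls, ref$genes)
  expect_equal(res$gene_id[1], "GENE003")
  expect_true(res$concordant[1])
  total <- res$hap_a_sum[1] + res$hap_b_sum[1]
  expect_gte(total, 200)
  se <- sqrt(0.9 * 0.1 / total)
  expect_lt(abs(res$hap_a_fraction[1] - 0.9), 3 * se)
})

test_that("isoform assignment keeps transcripts with testable exonic SNPs", {
  feats <- rbind(
    data.frame(contig = "chr1", start = c(1, 501), end = c(100, 600),
               strand = "+", feature = "exon", gene_id = "G1",
               transcript_id = "T1"),
    data.frame(contig = "chr1", start = 501, end = 600, strand = "+",
               feature = "exon", gene_id = "G1", transcript_id = "T2"))
  counts <- rbind(make_counts(19, 1, pos = 50),    # exon of T1 only
                  make_counts(4, 16, pos = 550),   # exon of T1 and T2
                  make_counts(18, 2, pos = 300))   # intronic
  iso <- map_snps_to_isoforms(calls_from_counts(counts), feats)
  expect_setequal(iso$transcripts$transcript_id, c("T1", "T2"))
  expect_equal(iso$transcripts$n_snps[iso$transcripts$transcript_id ==
                                        "T1"], 2L)
  expect_equal(iso$transcripts$n_snps[iso$transcripts$transcript_id ==
                                        "T2"], 1L)
  expect_false(300 %in% iso$assignments$pos)
  # discordant directions across the same transcript are flagged
  expect_true(iso$transcripts$discordant[
    iso$transcripts$transcript_id == "T1"])
  # a transcript with no testable exonic SNP disappears
  iso2 <- map_snps_to_isoforms(calls_from_counts(make_counts(19, 1,
                                                             pos = 300)),
                               feats)
  expect_equal(nrow(iso2$transcripts), 0L)
})

test_that("replicated-ASE overlap rises with the depth threshold", {
  overlaps <- matrix(NA_real_, nrow = 6, ncol = 3)
  for (s in 1:6) {
    truth_rf <- rep(c(0.5, 0.68, 0.32), times = c(700, 150, 150))
    set.seed(1000 + s)
    depths <- sample(rep(c(15, 60, 120), length.out = 1000))
    r1 <- calls_from_counts(simulate_site_counts(truth_rf, depths, 1000,
                                                 seed = 2000 + s))
    r2 <- calls_from_counts(simulate_site_counts(truth_rf, depths, 1000,
                                                 seed = 3000 + s))
    cmp <- compare_replicates(r1, r2, thresholds = c(10, 50, 100))
    overlaps[s, ] <- cmp$overlap_of_either
  }
  pooled <- colMeans(overlaps, na.rm = TRUE)
  expect_true(all(diff(pooled) >= 0))
})
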