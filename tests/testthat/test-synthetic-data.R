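test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(snp_rate = 1.5), "snp_rate")
  expect_error(sim_config(read_length = 0), "read_length")
  expect_error(sim_config(allelic_ratio_map = c(2)), "named")
  expect_error(sim_config(allelic_ratio_map = c(G1 = 2)), "ratios")
})

test_that("reference generation is seed-deterministic and seed-sensitive", {
  cfg <- small_config(seed = 1)
  a <- generate_toy_reference(cfg)
  b <- generate_toy_reference(small_config(seed = 1))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$features, b$features)
  d <- generate_toy_reference(small_config(seed = 2))
  expect_false(identical(as.character(a$genome),
                         as.character(d$genome)))
  expect_equal(nrow(a$genes), 2L)
  # gene models do not overlap
  expect_true(a$genes$start[2] > a$genes$end[1])
  # every feature class is representable
  expect_setequal(unique(a$features$feature),
                  c("exon", "CDS", "five_prime_utr", "three_prime_utr"))
})

test_that("degenerate references: no genes, and sizing errors", {
  r <- generate_toy_reference(small_config(n_genes = 0))
  expect_equal(nrow(r$genes), 0L)
  expect_equal(nrow(r$features), 0L)
  expect_equal(sum(Biostrings::width(r$genome)), 20000L)
  expect_error(generate_toy_reference(small_config(genome_length = 2000,
                                                   n_genes = 4)),
               "too short")
})

test_that("variant planting respects zygosity, phasing and indel knobs", {
  cfg <- small_config(het_fraction = 1, unphased_fraction = 0,
                      indel_count = 3)
  ref <- generate_toy_reference(cfg)
  v <- plant_phased_variants(ref, cfg)
  expect_true(all(v$phased$zygosity == "het"))
  expect_equal(nrow(v$unphased_snvs), 0L)
  expect_equal(nrow(v$indels), 3L)
  # het SNPs carry haplotype assignment with exactly one allele = ref
  het <- v$phased[v$phased$zygosity == "het", ]
  expect_true(all((het$hap_a == het$ref) != (het$hap_b == het$ref)))
  # indels never fall inside exons
  ex <- ref$features[ref$features$feature == "exon", ]
  for (i in seq_len(nrow(v$indels))) {
    expect_false(any(ex$contig == v$indels$contig[i] &
                       ex$start <= v$indels$pos[i] +
                         nchar(v$indels$ref[i]) &
                       ex$end >= v$indels$pos[i]))
  }
  # excessive rate raises the collision error
  expect_error(plant_phased_variants(ref, small_config(snp_rate = 0.3)),
               "collision")
})

test_that("every planted het SNP is in exactly one of phased/un-phased", {
  for (seed in 1:3) {
    cfg <- small_config(seed = seed, het_fraction = 0.8,
                        unphased_fraction = 0.3)
    ref <- generate_toy_reference(cfg)
    v <- plant_phased_variants(ref, cfg)
    het_truth <- paste(v$truth$contig, v$truth$pos)
    phased_het <- v$phased[v$phased$zygosity == "het", ]
    in_phased <- het_truth %in% paste(phased_het$contig, phased_het$pos)
    in_unph <- het_truth %in% paste(v$unphased_snvs$contig,
                                    v$unphased_snvs$pos)
    expect_true(all(xor(in_phased, in_unph)))
    expect_identical(v$truth$phased, in_phased)
  }
})

test_that("allelic ratio 1 sends every read to haplotype A", {
  cfg <- small_config(allelic_ratio_map = c(GENE001 = 1, GENE002 = 1))
  ref <- generate_toy_reference(cfg)
  v <- plant_phased_variants(ref, cfg)
  sim <- simulate_allelic_reads(ref, v, cfg)
  expect_true(all(sim$reads$hap == "A"))
})

test_that("read simulation reproduces the configured allelic ratio", {
  cfg <- small_config(n_genes = 1, fragment_depth = 200,
                      unphased_fraction = 0, base_error_rate = 0)
  ref <- generate_toy_reference(cfg)
  v <- plant_phased_variants(ref, cfg)
  sim <- simulate_allelic_reads(ref, v, cfg)
  merged <- merge_alignment_sets(alignment_set(sim$reads, "maternal"),
                                 alignment_set(sim$reads, "paternal"),
                                 alignment_set(sim$reads, "universal"))
  sites <- v$truth[v$truth$exonic & v$truth$phased, ]
  counts <- pileup_counts(merged$alignments, sites)
  # per-SNP haplotype-A read fraction within 3 binomial SE of 0.5
  t <- counts[counts$testable, ]
  hap_frac <- t$hap_a_count / (t$hap_a_count + t$hap_b_count)
  se <- sqrt(0.25 / (t$hap_a_count + t$hap_b_count))
  expect_true(all(abs(hap_frac - 0.5) <= 3 * se + 1e-12))
})

test_that("edit distances reflect true haplotype provenance", {
  cfg <- small_config(base_error_rate = 0, unphased_fraction = 0)
  ref <- generate_toy_reference(cfg)
  v <- plant_phased_variants(ref, cfg)
  sim <- simulate_allelic_reads(ref, v, cfg)
  r <- sim$reads
  # a read from its own haplotype has edit distance 0 at error rate 0
  expect_true(all(r$nm_maternal[r$hap == "A"] == 0))
  expect_true(all(r$nm_paternal[r$hap == "B"] == 0))
  # universal-space NM exceeds own-haplotype NM by >= 1 for reads
  # spanning a het SNP whose allele differs from the reference
  hapB_spanning <- r$hap == "B" & r$nm_universal > 0
  expect_true(all(r$nm_universal[hapB_spanning] >
                    r$nm_paternal[hapB_spanning]))
})

test_that("direct count draws are deterministic and calibrated", {
  a <- simulate_site_counts(0.5, 100, 1000, seed = 7)
  b <- simulate_site_counts(0.5, 100, 1000, seed = 7)
  expect_identical(a, b)
  expect_true(all(simulate_site_counts(1, 10, 50, seed = 1)$ref_count ==
                    10))
  big <- simulate_site_counts(0.5, 100, 10000, seed = 2)
  se <- sqrt(0.25 / 100) / sqrt(10000)
  expect_lt(abs(mean(big$ref_fraction) - 0.5), 3 * se)
})

test_that("fixture files conserve read counts across formats", {
  cfg <- small_config(fragment_depth = 10)
  ref <- generate_toy_reference(cfg)
  v <- plant_phased_variants(ref, cfg)
  sim <- simulate_allelic_reads(ref, v, cfg)
  dir <- withr::local_tempdir()
  fx <- write_sim_fixture(ref, v, sim, dir)
  n_pairs <- length(unique(sim$reads$qname))
  expect_equal(length(readLines(fx$fastq_r1)) / 4L, n_pairs)
  for (o in c("maternal", "paternal", "universal")) {
    al <- read_sam(fx[[paste0(o, "_sam")]])
    expect_equal(nrow(al), 2L * n_pairs)
    # NM tags round-trip for mapped records
    orig <- alignment_set(sim$reads, o)
    key <- paste(al$qname, al$mate)
    expect_equal(al$nm[match(paste(orig$qname, orig$mate), key)],
                 orig$nm)
  }
  # VCF round trip preserves phase
  ph <- read_vcf_variants(fx$phased_vcf)
  orig <- v$phased[order(v$phased$contig, v$phased$pos), ]
  expect_equal(ph$pos, orig$pos)
  expect_equal(ph$hap_a, orig$hap_a)
  expect_equal(ph$zygosity, orig$zygosity)
})
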