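test_that("selection follows NM sums, universal ties and mapping state", {
  # smallest sum of edit distances wins
  t1 <- rbind(cand("maternal", nm1 = 1, nm2 = 0),
              cand("paternal", nm1 = 2, nm2 = 1),
              cand("universal", nm1 = 1, nm2 = 1))
  expect_equal(choose_alignment(t1),
               list(origin = "maternal", reason = "fewest_mismatches"))
  # ties go to universal
  t2 <- rbind(cand("maternal", nm1 = 1, nm2 = 1),
              cand("paternal", nm1 = 2, nm2 = 0),
              cand("universal", nm1 = 0, nm2 = 2))
  expect_equal(choose_alignment(t2),
               list(origin = "universal", reason = "tie_universal"))
  # a mapped pair beats a lower-NM candidate with an unmapped mate
  t3 <- rbind(cand("maternal", m2 = FALSE, nm1 = 0),
              cand("universal", nm1 = 2, nm2 = 2))
  expect_equal(choose_alignment(t3),
               list(origin = "universal",
                    reason = "mapped_pair_preferred"))
  # maternal/paternal tie resolves to maternal, deterministically
  t4 <- rbind(cand("maternal", nm1 = 1, nm2 = 0),
              cand("paternal", nm1 = 0, nm2 = 1),
              cand("universal", nm1 = 2, nm2 = 1))
  expect_equal(choose_alignment(t4)$origin, "maternal")
  # nothing mapped anywhere -> universal, only_candidate
  t5 <- rbind(cand("maternal", m1 = FALSE, m2 = FALSE),
              cand("universal", m1 = FALSE, m2 = FALSE))
  expect_equal(choose_alignment(t5),
               list(origin = "universal", reason = "only_candidate"))
})

test_that("selection matches the rule-table oracle over exhaustive triples", {
  states <- expand.grid(m1 = c(TRUE, FALSE), m2 = c(TRUE, FALSE),
                        nm1 = 0:3, nm2 = 0:3)
  states <- states[!(duplicated(paste(states$m1, states$m2,
                                      ifelse(states$m1, states$nm1, -1),
                                      ifelse(states$m2, states$nm2,
                                             -1)))), ]
  idx <- seq_len(nrow(states))
  set.seed(42)
  combos <- expand.grid(a = idx, b = idx)
  combos <- combos[sample.int(nrow(combos), 400), ]
  for (r in seq_len(nrow(combos))) {
    sa <- states[combos$a[r], ]
    sb <- states[combos$b[r], ]
    triple <- rbind(cand("maternal", sa$m1, sa$m2, sa$nm1, sa$nm2),
                    cand("universal", sb$m1, sb$m2, sb$nm1, sb$nm2))
    expect_equal(choose_alignment(triple)$origin, oracle_choose(triple),
                 info = paste("pair case", r))
  }
  # full three-way enumeration on a coarser NM grid
  small <- states[states$nm1 <= 1 & states$nm2 <= 1, ]
  si <- seq_len(nrow(small))
  for (a in si) for (b in si) for (cc in si) {
    triple <- rbind(cand("maternal", small$m1[a], small$m2[a],
                         small$nm1[a], small$nm2[a]),
                    cand("paternal", small$m1[b], small$m2[b],
                         small$nm1[b], small$nm2[b]),
                    cand("universal", small$m1[cc], small$m2[cc],
                         small$nm1[cc], small$nm2[cc]))
    expect_equal(choose_alignment(triple)$origin, oracle_choose(triple))
  }
})

test_that("merging tags origins, conserves reads and matches per-triple choice", {
  cfg <- small_config(fragment_depth = 20, base_error_rate = 0.002)
  ref <- generate_toy_reference(cfg)
  v <- plant_phased_variants(ref, cfg)
  sim <- simulate_allelic_reads(ref, v, cfg)
  sets <- lapply(c("maternal", "paternal", "universal"),
                 function(o) alignment_set(sim$reads, o))
  merged <- merge_alignment_sets(sets[[1]], sets[[2]], sets[[3]])

  # conservation: each qname appears at most once (pair = 2 records)
  expect_true(all(table(merged$alignments$qname) <= 2))
  expect_setequal(unique(merged$decisions$qname),
                  unique(sim$reads$qname))
  expect_true(all(merged$alignments$zr ==
                    paste0("ZR:Z:", merged$alignments$origin)))

  # vectorized merge agrees with the scalar rule on every triple
  for (q in sample(unique(sim$reads$qname), 50)) {
    triple <- do.call(rbind, lapply(
      c("maternal", "paternal", "universal"), function(o) {
        s <- sets[[match(o, c("maternal", "paternal", "universal"))]]
        s <- s[s$qname == q, ]
        data.frame(origin = o,
                   mate1_mapped = s$mapped[s$mate == 1],
                   mate2_mapped = s$mapped[s$mate == 2],
                   nm1 = s$nm[s$mate == 1], nm2 = s$nm[s$mate == 2])
      }))
    expect_equal(
      merged$decisions$origin[merged$decisions$qname == q],
      choose_alignment(triple)$origin, info = q)
  }
})

test_that("a read present in a single stream is emitted from it", {
  pair <- make_pair("r1", nm = 1L)
  pair$nm <- 1L
  merged <- merge_alignment_sets(empty_set(), empty_set(), pair)
  expect_equal(unique(merged$alignments$origin), "universal")
  expect_equal(merged$decisions$reason, "only_candidate")
  # empty everything
  m0 <- merge_alignment_sets(empty_set(), empty_set(), empty_set())
  expect_equal(nrow(m0$alignments), 0L)
})

test_that("malformed NM on a mapped record demotes it to unmapped", {
  pair <- make_pair("r1")
  pair$nm <- c(NA, 0L)
  uni <- make_pair("r1", pos1 = 100L, pos2 = 250L)
  uni$nm <- c(3L, 3L)
  expect_warning(
    merged <- merge_alignment_sets(pair, empty_set(), uni),
    "malformed NM")
  expect_equal(merged$decisions$origin, "universal")
  expect_equal(merged$decisions$reason, "mapped_pair_preferred")
})

test_that("filtering removes duplicates, multimappers, low MAPQ and chrM", {
  base <- rbind(
    make_pair("a", pos1 = 100, pos2 = 250),
    make_pair("a_dup", pos1 = 100, pos2 = 250, mapq = 50),
    make_pair("b", pos1 = 300, pos2 = 450, mapq = 9),
    make_pair("c", pos1 = 500, pos2 = 650, mapq = 8),
    make_pair("d", pos1 = 700, pos2 = 850, multimapped = TRUE),
    make_pair("m", contig = "chrM", pos1 = 10, pos2 = 160))
  res <- filter_alignments(base)
  kept <- unique(res$alignments$qname)
  expect_setequal(kept, c("a", "b"))
  expect_equal(unname(res$tally["duplicate"]), 2L)      # the lower-MAPQ pair
  expect_equal(unname(res$tally["multimapped"]), 2L)
  expect_equal(unname(res$tally["low_mapq"]), 2L)       # MAPQ 8 only
  expect_equal(unname(res$tally["mitochondrial"]), 2L)
})
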