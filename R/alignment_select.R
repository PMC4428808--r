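ORIGINS <- c("universal", "maternal", "paternal")  # tie-break preference

#' Choose the best alignment among maternal/paternal/universal candidates
#'
#' Implements the pairwise alignment-selection rules of the diploid
#' alignment method, in precedence order:
#' 1. a candidate with more mapped mates beats one with fewer (a fully
#'    mapped pair is preferred over any candidate with an unmapped mate);
#' 2. among equally-mapped candidates, the smallest sum of edit distances
#'    (SAM `NM` values over mapped mates) wins;
#' 3. ties are broken in favour of the universal alignment; a residual
#'    maternal/paternal tie goes to maternal (deterministic convention,
#'    reported with reason `"fewest_mismatches"` since it is a tied
#'    minimum).
#'
#' A triple where no candidate maps any mate resolves to universal when
#' supplied (else the first supplied origin) with reason
#' `"only_candidate"`.
#'
#' @param triple data.frame with one row per candidate origin and columns
#'   `origin`, `mate1_mapped`, `mate2_mapped`, `nm1`, `nm2` (`NA` when the
#'   mate is unmapped).
#' @return list with `origin` and `reason` (one of `fewest_mismatches`,
#'   `tie_universal`, `mapped_pair_preferred`, `only_candidate`).
#' @examples
#' triple <- data.frame(origin = c("maternal", "paternal", "universal"),
#'                      mate1_mapped = TRUE, mate2_mapped = TRUE,
#'                      nm1 = c(0, 2, 1), nm2 = c(1, 1, 1))
#' choose_alignment(triple)  # maternal, fewest_mismatches
#' @export
choose_alignment <- function(triple) {
  stopifnot(nrow(triple) >= 1L,
            all(triple$origin %in% ORIGINS),
            !anyDuplicated(triple$origin))
  n_mapped <- as.integer(triple$mate1_mapped) +
    as.integer(triple$mate2_mapped)
  nm_sum <- ifelse(triple$mate1_mapped, triple$nm1, 0L) +
    ifelse(triple$mate2_mapped, triple$nm2, 0L)

  if (all(n_mapped == 0L)) {
    origin <- if ("universal" %in% triple$origin) "universal"
    else triple$origin[1]
    return(list(origin = origin, reason = "only_candidate"))
  }
  if (nrow(triple) == 1L)
    return(list(origin = triple$origin, reason = "only_candidate"))

  tier <- n_mapped == max(n_mapped)
  if (sum(tier) == 1L)
    return(list(origin = triple$origin[tier],
                reason = "mapped_pair_preferred"))

  nm_eff <- ifelse(tier, nm_sum, Inf)
  tied <- which(nm_eff == min(nm_eff))
  if (length(tied) == 1L)
    return(list(origin = triple$origin[tied],
                reason = "fewest_mismatches"))
  tied_origins <- triple$origin[tied]
  if ("universal" %in% tied_origins)
    return(list(origin = "universal", reason = "tie_universal"))
  winner <- ORIGINS[min(match(tied_origins, ORIGINS))]
  list(origin = winner, reason = "fewest_mismatches")
}

#' Merge three alignment sets into an origin-tagged diploid alignment
#'
#' Collates the maternal, paternal and universal alignment tables by read
#' name, applies [choose_alignment()]'s rules (vectorized) to every read
#' pair, and emits the chosen records tagged with their origin (the
#' `zr` column, mirroring the SAM tag `ZR:Z:<origin>`). Coordinates of the
#' chosen records are valid against the universal reference because the
#' haplotype genomes are coordinate-identical (SNP-only substitution).
#'
#' @param maternal,paternal,universal alignment data.frames in the
#'   standard layout (see [alignment_set()]); any may be empty.
#' @return list with `alignments` (chosen records, plus `origin` and `zr`
#'   columns) and `decisions` (per-read qname, origin, reason).
#' @export
merge_alignment_sets <- function(maternal, paternal, universal) {
  sets <- list(maternal = maternal, paternal = paternal,
               universal = universal)
  sets <- lapply(sets, sanitize_alignments)

  qnames <- unique(unlist(lapply(sets, function(s) s$qname),
                          use.names = FALSE))
  if (!length(qnames)) {
    al <- empty_alignments(); al$origin <- character(0); al$zr <- character(0)
    return(list(alignments = al,
                decisions = data.frame(qname = character(0),
                                       origin = character(0),
                                       reason = character(0),
                                       stringsAsFactors = FALSE)))
  }

  nmap <- nmsum <- matrix(NA_real_, length(qnames), 3,
                          dimnames = list(qnames,
                                          c("maternal", "paternal",
                                            "universal")))
  for (o in colnames(nmap)) {
    s <- sets[[o]]
    if (!nrow(s)) next
    idx <- match(s$qname, qnames)
    nm_ok <- ifelse(s$mapped, s$nm, 0)
    agg_map <- rowsum(as.integer(s$mapped), idx)
    agg_nm <- rowsum(nm_ok, idx)
    rows <- as.integer(rownames(agg_map))
    nmap[rows, o] <- agg_map[, 1]
    nmsum[rows, o] <- agg_nm[, 1]
  }

  present <- !is.na(nmap)
  n_supplied <- rowSums(present)
  tier <- apply(nmap, 1L, max, na.rm = TRUE)
  eligible <- present & nmap == tier & !is.na(nmap)
  nm_eff <- ifelse(eligible, nmsum, Inf)
  min_nm <- apply(nm_eff, 1L, min)
  tied <- nm_eff == min_nm

  pref <- c(universal = 1L, maternal = 2L, paternal = 3L)
  rank <- matrix(rep(pref[colnames(tied)], each = nrow(tied)),
                 nrow = nrow(tied))
  rank[!tied] <- NA_integer_
  pick <- apply(rank, 1L, which.min)
  chosen <- colnames(tied)[pick]

  # degenerate: nothing mapped anywhere -> universal if supplied
  all_unmapped <- tier == 0
  if (any(all_unmapped)) {
    fix <- all_unmapped & present[, "universal"]
    chosen[fix] <- "universal"
    no_uni <- all_unmapped & !present[, "universal"]
    if (any(no_uni))
      chosen[no_uni] <- apply(present[no_uni, , drop = FALSE], 1L,
                              function(p) colnames(present)[p][1])
  }

  n_tied <- rowSums(tied)
  n_eligible <- rowSums(eligible)
  reason <- ifelse(
    n_supplied == 1L | all_unmapped, "only_candidate",
    ifelse(n_eligible == 1L, "mapped_pair_preferred",
           ifelse(n_tied > 1L & chosen == "universal", "tie_universal",
                  "fewest_mismatches")))

  decisions <- data.frame(qname = qnames, origin = unname(chosen),
                          reason = unname(reason),
                          stringsAsFactors = FALSE)

  merged <- lapply(c("maternal", "paternal", "universal"), function(o) {
    q <- qnames[chosen == o]
    s <- sets[[o]]
    s <- s[s$qname %in% q, , drop = FALSE]
    # a read chosen from an origin it is absent from cannot happen for
    # mapped tiers; for the degenerate all-unmapped fallback emit what
    # exists in the fallback origin only
    if (nrow(s)) { s$origin <- o; s$zr <- paste0("ZR:Z:", o) }
    s
  })
  merged <- do.call(rbind, merged[vapply(merged, nrow, integer(1)) > 0])
  if (is.null(merged)) {
    merged <- empty_alignments(); merged$origin <- character(0)
    merged$zr <- character(0)
  }
  missing <- setdiff(qnames, unique(merged$qname))
  if (length(missing))
    warning(length(missing), " read(s) had no records in their chosen ",
            "origin and were skipped")
  rownames(merged) <- NULL
  list(alignments = merged, decisions = decisions)
}

sanitize_alignments <- function(s) {
  if (is.null(s)) return(empty_alignments())
  need <- c("qname", "mate", "mapped", "nm")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("alignment table lacks column(s): ", paste(miss, collapse = ", "))
  bad_nm <- s$mapped & (is.na(s$nm) | s$nm < 0)
  if (any(bad_nm)) {
    warning(sum(bad_nm), " record(s) with malformed NM treated as unmapped")
    s$mapped[bad_nm] <- FALSE
    s$nm[bad_nm] <- NA_integer_
  }
  s
}

#' Filter a merged diploid alignment
#'
#' Applies the post-merge cleanup: PCR-duplicate removal (identical
#' contig, unclipped start, strand and mate start; the highest-MAPQ pair
#' is retained, ties to the first encountered), removal of multi-mapped
#' records, of records with mapping quality below `min_mapq`, and of all
#' records on the mitochondrial contig.
#'
#' @param alignments merged alignment data.frame
#'   (see [merge_alignment_sets()]).
#' @param min_mapq minimum mapping quality kept (default 9, i.e. MAPQ < 9
#'   removed).
#' @param mito_name mitochondrial contig name (default `"chrM"`); a
#'   warning is issued if absent from the data.
#' @param warn_missing_mito warn when `mito_name` does not occur.
#' @return list with `alignments` (kept records) and `tally` (named
#'   integer vector of records removed per category, in application
#'   order: duplicate, multimapped, low_mapq, mitochondrial).
#' @export
filter_alignments <- function(alignments, min_mapq = 9L,
                              mito_name = "chrM",
                              warn_missing_mito = FALSE) {
  al <- alignments
  tally <- c(duplicate = 0L, multimapped = 0L, low_mapq = 0L,
             mitochondrial = 0L)
  if (!nrow(al)) return(list(alignments = al, tally = tally))

  # duplicates: key pairs on mate-1 coordinates and mate start
  m1 <- al[al$mate == 1L & al$mapped, , drop = FALSE]
  if (nrow(m1)) {
    key <- paste(m1$contig, m1$pos, m1$strand, m1$mate_pos)
    ord <- order(-m1$mapq, seq_len(nrow(m1)))
    keep_q <- m1$qname[ord][!duplicated(key[ord])]
    dup_q <- setdiff(m1$qname, keep_q)
    drop <- al$qname %in% dup_q
    tally["duplicate"] <- sum(drop)
    al <- al[!drop, , drop = FALSE]
  }

  drop <- al$multimapped %in% TRUE
  tally["multimapped"] <- sum(drop)
  al <- al[!drop, , drop = FALSE]

  drop <- al$mapq < min_mapq
  tally["low_mapq"] <- sum(drop, na.rm = TRUE)
  al <- al[!(drop %in% TRUE), , drop = FALSE]

  if (warn_missing_mito && !any(alignments$contig == mito_name))
    warning("mitochondrial contig '", mito_name, "' not present")
  drop <- al$contig == mito_name
  tally["mitochondrial"] <- sum(drop)
  al <- al[!drop, , drop = FALSE]

  rownames(al) <- NULL
  list(alignments = al, tally = tally)
}
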