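#' Exact two-sided binomial test p-value
#'
#' Probability, under Binomial(n, p), of observing an outcome at most as
#' likely as `k`. Two conventions are offered:
#' * `"min_likelihood"` (default): sum of binomial probabilities over all
#'   outcomes whose probability does not exceed that of `k` (with a
#'   1 + 1e-7 relative slack against floating-point ties). This is the
#'   common definition in scientific software and is well defined for
#'   asymmetric expected proportions.
#' * `"tail_doubling"`: twice the smaller tail probability, capped at 1.
#'
#' @param k observed successes (vectorized).
#' @param n trials.
#' @param p expected success proportion, strictly inside (0, 1).
#' @param method two-sided construction.
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' binomial_two_sided(5, 10, 0.5)   # 1
#' binomial_two_sided(0, 10, 0.5)   # 2/1024
#' binomial_two_sided(2, 10, 0.5)   # 112/1024
#' @export
binomial_two_sided <- function(k, n, p,
                               method = c("min_likelihood",
                                          "tail_doubling")) {
  method <- match.arg(method)
  len <- max(length(k), length(n), length(p))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  p <- rep_len(as.numeric(p), len)
  if (any(is.na(k) | is.na(n) | is.na(p)))
    stop("NA passed to binomial_two_sided")
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
  if (any(p <= 0 | p >= 1))
    stop("expected proportion must be strictly inside (0, 1)")

  # many sites share (k, n, p); evaluate unique triples once
  key <- paste(k, n, p)
  uniq <- !duplicated(key)
  pv_u <- vapply(which(uniq), function(i) {
    if (method == "tail_doubling") {
      lo <- pbinom(k[i], n[i], p[i])
      hi <- pbinom(k[i] - 1, n[i], p[i], lower.tail = FALSE)
      return(min(1, 2 * min(lo, hi)))
    }
    d <- dbinom(0:n[i], n[i], p[i])
    min(1, sum(d[d <= d[k[i] + 1] * (1 + 1e-7)]))
  }, numeric(1))
  unname(pv_u[match(key, key[uniq])])
}

#' Per-library ordered-genotype median reference fractions
#'
#' The expected reference fraction of a SNP is not assumed to be 0.5:
#' residual allele-specific biases differ by ordered genotype (the
#' specific reference-variant base combination, 12 possible values). This
#' computes, per library, the median observed reference fraction over all
#' testable SNPs in each ordered-genotype bin, plus a library-wide
#' fallback median for bins unpopulated at small scale.
#'
#' @param counts site-counts data.frame (see [pileup_counts()]) with
#'   `library_id`, `ref`, `alt`, `ref_fraction`, `testable` columns.
#' @return list of class `bin_median_table` with `bins` (library_id,
#'   genotype, median_rf, n) and `fallback` (library_id, median_rf).
#' @export
compute_bin_medians <- function(counts) {
  use <- counts[counts$testable %in% TRUE & !is.na(counts$ref_fraction), ,
                drop = FALSE]
  if (!nrow(use)) stop("no testable sites; cannot compute bin medians")
  use$genotype <- paste0(use$ref, ">", use$alt)
  libs <- unique(counts$library_id)
  missing_lib <- setdiff(libs, unique(use$library_id))
  if (length(missing_lib))
    stop("library without testable sites: ",
         paste(missing_lib, collapse = ", "))

  bins <- do.call(rbind, lapply(split(use, use[c("genotype", "library_id")],
                                      drop = TRUE), function(d) {
    data.frame(library_id = d$library_id[1], genotype = d$genotype[1],
               median_rf = median(d$ref_fraction), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  fallback <- do.call(rbind, lapply(split(use, use$library_id),
                                    function(d) {
    data.frame(library_id = d$library_id[1],
               median_rf = median(d$ref_fraction),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- rownames(fallback) <- NULL
  structure(list(bins = bins, fallback = fallback),
            class = "bin_median_table")
}

#' @export
print.bin_median_table <- function(x, ...) {
  cat("bin_median_table:", nrow(x$bins), "genotype bin(s) across",
      nrow(x$fallback), "library(ies)\n")
  invisible(x)
}

#' Classify per-SNP allele-specific expression
#'
#' A testable SNP is classified ASE when its observed reference fraction
#' lies outside the expected (bin-median) fraction by more than
#' `delta_threshold` *and* the two-sided binomial probability of its
#' reference count, with the expected proportion set to that median, is
#' at most `alpha`. Using both criteria rejects highly expressed SNPs
#' with slight imbalance and lowly expressed SNPs with large imbalance.
#' Direction is reported against haplotype (toward_hapA/toward_hapB,
#' balanced on equality) so that within-gene concordance is phase-aware.
#'
#' @param counts site-counts data.frame (see [pileup_counts()]).
#' @param medians a `bin_median_table` from [compute_bin_medians()].
#' @param delta_threshold minimum |observed - expected| reference
#'   fraction (default 0.15).
#' @param alpha p-value ceiling (default 0.05).
#' @param min_depth testability depth (default 10).
#' @param method two-sided convention, see [binomial_two_sided()].
#' @param fdr_column add a Benjamini-Hochberg adjusted p-value column
#'   (off by default: the design pairs a raw p <= alpha with the
#'   effect-size rule).
#' @return the input with appended columns `expected_rf`, `delta`,
#'   `p_value`, `class` ("ASE"/"not_ASE"/"untestable") and `direction`.
#' @export
classify_snp_ase <- function(counts, medians, delta_threshold = 0.15,
                             alpha = 0.05, min_depth = 10L,
                             method = c("min_likelihood",
                                        "tail_doubling"),
                             fdr_column = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(medians, "bin_median_table"))
  genotype <- paste0(counts$ref, ">", counts$alt)
  bi <- match(paste(counts$library_id, genotype),
              paste(medians$bins$library_id, medians$bins$genotype))
  m <- medians$bins$median_rf[bi]
  fi <- match(counts$library_id, medians$fallback$library_id)
  m[is.na(m)] <- medians$fallback$median_rf[fi[is.na(m)]]
  if (any(is.na(m)))
    stop("no genotype-bin median and no fallback for library ",
         counts$library_id[is.na(m)][1])
  if (any(m <= 0 | m >= 1))
    stop("degenerate bin median (0 or 1); cannot form a binomial ",
         "expectation")

  n_inf <- counts$ref_count + counts$alt_count
  testable <- counts$depth >= min_depth
  p <- rep(NA_real_, nrow(counts))
  ok <- n_inf > 0
  p[ok] <- binomial_two_sided(counts$ref_count[ok], n_inf[ok], m[ok],
                              method = method)
  delta <- abs(counts$ref_fraction - m)
  cls <- ifelse(!testable, "untestable",
                ifelse(delta > delta_threshold & !is.na(p) & p <= alpha,
                       "ASE", "not_ASE"))
  direction <- ifelse(is.na(counts$hap_a_count) |
                        is.na(counts$hap_b_count), NA_character_,
                      ifelse(counts$hap_a_count > counts$hap_b_count,
                             "toward_hapA",
                             ifelse(counts$hap_a_count <
                                      counts$hap_b_count,
                                    "toward_hapB", "balanced")))
  out <- counts
  out$expected_rf <- m
  out$delta <- delta
  out$p_value <- p
  out$class <- cls
  out$direction <- direction
  if (fdr_column) {
    out$p_adj <- NA_real_
    t_idx <- which(cls != "untestable" & !is.na(p))
    out$p_adj[t_idx] <- p.adjust(p[t_idx], method = "BH")
  }
  out
}
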