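# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

#' Total reference-consumed width of a CIGAR string
#'
#' Sums the lengths of operations that consume reference bases
#' (M, D, N, =, X).
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of reference widths.
#' @keywords internal
#' @noRd
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    keep <- grepl("[MDN=X]$", ops)
    sum(as.integer(sub("[A-Z=]$", "", ops[keep])))
  }, integer(1), USE.NAMES = FALSE)
}

# summed length of M (alignment match) operations only
cigar_m_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    keep <- grepl("[M=X]$", ops)
    sum(as.integer(sub("[A-Z=]$", "", ops[keep])))
  }, integer(1), USE.NAMES = FALSE)
}

# TRUE when the CIGAR is a single M run (ungapped alignment)
cigar_is_simple <- function(cigar) grepl("^\\d+M$", cigar)

#' Count substitution mismatches encoded in an MD tag
#'
#' Deleted reference stretches (`^` followed by bases) are not mismatches;
#' every other reference base letter in the tag marks one substitution.
#' @param md character vector of MD tag values.
#' @return integer vector of mismatch counts; NA for missing tags.
#' @keywords internal
#' @noRd
md_mismatch_count <- function(md) {
  vapply(md, function(x) {
    if (is.na(x)) return(NA_integer_)
    x <- gsub("\\^[ACGTN]+", "", x)
    sum(strsplit(x, "")[[1]] %in% c("A", "C", "G", "T", "N"))
  }, integer(1), USE.NAMES = FALSE)
}

# hamming distance between equal-length strings (vectorized)
str_mismatches <- function(a, b) {
  stopifnot(length(a) == length(b))
  vapply(seq_along(a), function(i) {
    ra <- charToRaw(a[[i]])
    rb <- charToRaw(b[[i]])
    if (length(ra) != length(rb))
      stop("sequence length mismatch in mismatch count")
    sum(ra != rb)
  }, integer(1))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# coerce a DNAStringSet / named character vector to named character
as_seq_chars <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    if (is.null(names(x))) stop("reference sequences must be named")
    x
  } else {
    stop("reference must be a DNAStringSet or a named character vector")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
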