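# Canonical internal alphabet is DNA (A, C, G, T); RNA input (U) is mapped to
# T so that motifs from SELEX RNA, nascent RNA reads and genomic promoter
# sequence are directly comparable. Ambiguous bases are kept as N and treated
# as unscoreable/never-matching downstream.
NBE_BASES <- c("A", "C", "G", "T")

# Fast per-character lookup: byte value -> base index 1..4, NA otherwise.
.base_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt("U")] <- 4L; lut[utf8ToInt("u")] <- 4L
  lut
})

#' Canonicalize a nucleotide string
#'
#' Uppercases, converts RNA U to T, and validates the alphabet. Characters
#' outside A/C/G/T/U and the ambiguity code N are rejected.
#'
#' @param x character vector of nucleotide strings.
#' @param allow_ambiguous keep `N` characters (default `TRUE`); if `FALSE`,
#'   any `N` is an error.
#' @return character vector over the alphabet A, C, G, T (and N).
#' @export
canonicalize_seq <- function(x, allow_ambiguous = TRUE) {
  stopifnot(is.character(x))
  out <- chartr("acgtuU", "ACGTTT", toupper(x))
  bad <- grepl(if (allow_ambiguous) "[^ACGTN]" else "[^ACGT]", out)
  if (any(bad)) {
    stop("invalid nucleotide character in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  out
}

# String -> integer codes 1..4 (NA for N). Input need not be canonicalized.
seq_to_int <- function(s) {
  .base_lut[utf8ToInt(s)]
}

int_to_seq <- function(idx) {
  paste(NBE_BASES[idx], collapse = "")
}

# Reverse complement on the canonical DNA alphabet.
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(canonicalize_seq(s),
                                              "")[[1L]]), collapse = ""))
}
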