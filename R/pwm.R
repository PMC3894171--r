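#' Build a log-likelihood position weight matrix from a consensus motif
#'
#' The motif model places probability `match_probability` on the consensus
#' base at each position and splits the remaining mass equally over the other
#' three bases. Scores are log2 likelihood ratios against a background base
#' distribution, so a k-mer score is in bits and the consensus k-mer is the
#' unique global maximum.
#'
#' @param consensus consensus motif as a nucleotide string (DNA or RNA;
#'   U is canonicalized to T). Default is the NELF-E binding element.
#' @param match_probability probability of the consensus base per position;
#'   must lie strictly between 0.25 and 1.
#' @param background length-4 base probability vector (A, C, G, T order, or
#'   named); strictly positive, summing to 1.
#' @return an object of class `nbe_pwm`: a k x 4 numeric matrix of scores in
#'   bits (rows = motif positions, columns A/C/G/T) with attributes
#'   `consensus`, `match_probability` and `background`.
#' @examples
#' pwm <- build_pwm("CUGAGGA", match_probability = 0.85)
#' score_kmer(pwm, "CTGAGGA")
#' @export
build_pwm <- function(consensus = "CUGAGGA", match_probability = 0.85,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!is.numeric(match_probability) || length(match_probability) != 1L ||
      !is.finite(match_probability) ||
      match_probability <= 0.25 || match_probability >= 1) {
    stop("match_probability must be a finite number in (0.25, 1)")
  }
  background <- .check_background(background)
  cons <- canonicalize_seq(consensus, allow_ambiguous = FALSE)
  idx <- seq_to_int(cons)
  k <- length(idx)
  if (k < 1L) stop("consensus must have length >= 1")

  probs <- matrix((1 - match_probability) / 3, nrow = k, ncol = 4L,
                  dimnames = list(NULL, NBE_BASES))
  probs[cbind(seq_len(k), idx)] <- match_probability
  scores <- log2(sweep(probs, 2L, background, "/"))
  # the consensus base must be the strict per-position maximum; with a
  # skewed background a too-small match probability would violate this
  cons_scores <- scores[cbind(seq_len(k), idx)]
  if (any(scores >= cons_scores - 1e-12 &
            col(scores) != idx[row(scores)])) {
    stop("match_probability ", match_probability, " is too small for this ",
         "background: the consensus base would not be the per-position ",
         "maximum")
  }
  structure(scores,
            consensus = cons,
            match_probability = match_probability,
            background = background,
            class = c("nbe_pwm", "matrix", "array"))
}

.check_background <- function(background) {
  if (length(background) != 4L || !is.numeric(background) ||
      any(!is.finite(background)) || any(background <= 0)) {
    stop("background must be 4 strictly positive probabilities")
  }
  if (!is.null(names(background))) {
    if (!setequal(names(background), NBE_BASES)) {
      stop("background names must be A, C, G, T")
    }
    background <- background[NBE_BASES]
  } else {
    names(background) <- NBE_BASES
  }
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  background
}

#' @export
print.nbe_pwm <- function(x, ...) {
  cat(sprintf("Log-likelihood PWM for consensus %s (match p = %.3g)\n",
              attr(x, "consensus"), attr(x, "match_probability")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

motif_length <- function(pwm) nrow(pwm)

#' Score a single k-mer against a PWM
#'
#' Sum of per-position log2 likelihood-ratio scores. A k-mer containing an
#' ambiguous base (N) is unscoreable and returns `NA`.
#'
#' @param pwm an `nbe_pwm` from [build_pwm()].
#' @param kmer nucleotide string whose length equals the motif length.
#' @return score in bits, or `NA_real_` for an ambiguous k-mer.
#' @export
score_kmer <- function(pwm, kmer) {
  idx <- seq_to_int(canonicalize_seq(kmer))
  if (length(idx) != motif_length(pwm)) {
    stop("k-mer length ", length(idx), " does not match motif length ",
         motif_length(pwm))
  }
  if (anyNA(idx)) return(NA_real_)
  .score_kmer_ints(pwm, idx)
}

# Scalar k-mer scorer with the same left-to-right double-precision
# accumulation as score_offsets_int, so scan scores and null scores of the
# same k-mer are bitwise identical (base::sum accumulates in long double
# and would differ in the last bits).
.score_kmer_ints <- function(pwm, idx) {
  k <- nrow(pwm)
  s <- 0
  for (i in seq_len(k)) s <- s + pwm[i + (idx[i] - 1L) * k]
  s
}

# Scores of every k-mer window of an integer-coded sequence (codes 1..4, NA
# for ambiguous). Returns a numeric vector of length L - k + 1; windows
# touching an NA are NA. Vectorized over offsets: k passes over the sequence.
score_offsets_int <- function(seq_int, pwm) {
  k <- motif_length(pwm)
  L <- length(seq_int)
  if (L < k) return(numeric(0L))
  n_off <- L - k + 1L
  total <- numeric(n_off)
  for (i in seq_len(k)) {
    b <- seq_int[i:(i + n_off - 1L)]
    total <- total + pwm[i + (b - 1L) * k]   # column-major index into k x 4
  }
  total
}

#' Score every k-mer window of a sequence
#'
#' @param pwm an `nbe_pwm`.
#' @param sequence a nucleotide string of length >= motif length.
#' @return numeric vector of window scores (bits), 5'-most base of each
#'   window defining its position; `NA` where the window contains an
#'   ambiguous base.
#' @export
score_windows <- function(pwm, sequence) {
  score_offsets_int(seq_to_int(canonicalize_seq(sequence)), pwm)
}

#' Write / read a PWM as TSV
#'
#' Plain-text serialization: columns `position`, `A`, `C`, `G`, `T` plus a
#' header comment carrying the consensus, match probability and background.
#'
#' @param pwm an `nbe_pwm`.
#' @param path file path.
#' @return `read_pwm_tsv` returns the reconstructed `nbe_pwm`.
#' @export
write_pwm_tsv <- function(pwm, path) {
  hdr <- sprintf("# consensus=%s match_probability=%.17g background=%s",
                 attr(pwm, "consensus"), attr(pwm, "match_probability"),
                 paste(sprintf("%.17g", attr(pwm, "background")), collapse = ","))
  df <- data.frame(position = seq_len(nrow(pwm)), unclass(pwm)[, NBE_BASES])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_pwm_tsv
#' @export
read_pwm_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "consensus=(\\S+) match_probability=(\\S+) background=(\\S+)", hdr))[[1L]]
  if (length(m) != 4L) stop("malformed PWM TSV header: ", path)
  build_pwm(m[2L], as.numeric(m[3L]),
            as.numeric(strsplit(m[4L], ",")[[1L]]))
}
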