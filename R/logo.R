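#' Sequence logo summary from aligned k-mers
#'
#' Computes per-position base frequencies and information content (2 - H,
#' with H the Shannon entropy in bits). No small-sample correction is
#' applied, so the summary is a deterministic function of the input k-mers.
#'
#' @param kmers character vector of equal-length nucleotide strings
#'   (unambiguous bases only).
#' @return an object of class `nbe_logo`: list with `freq` (L x 4 base
#'   frequency matrix), `ic_bits` (length-L information content, in [0, 2]),
#'   and `n` (number of k-mers).
#' @export
logo_from_kmers <- function(kmers) {
  if (length(kmers) == 0L) stop("at least one k-mer is required")
  kmers <- canonicalize_seq(kmers, allow_ambiguous = FALSE)
  L <- unique(nchar(kmers))
  if (length(L) != 1L) stop("k-mers must all have the same length")
  mat <- matrix(unlist(lapply(kmers, seq_to_int), use.names = FALSE),
                ncol = L, byrow = TRUE)
  freq <- vapply(seq_len(4L), function(b) colMeans(mat == b),
                 numeric(L))
  if (L == 1L) freq <- matrix(freq, nrow = 1L)
  colnames(freq) <- NBE_BASES
  h <- apply(freq, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(freq = freq, ic_bits = 2 - h, n = length(kmers)),
            class = "nbe_logo")
}

#' @export
print.nbe_logo <- function(x, ...) {
  cat(sprintf("Sequence logo summary over %d k-mers (length %d)\n",
              x$n, nrow(x$freq)))
  print(cbind(round(x$freq, 3), IC_bits = round(x$ic_bits, 3)))
  invisible(x)
}

#' Write a logo summary as TSV (position, A, C, G, T, IC_bits)
#'
#' @param logo an `nbe_logo` from [logo_from_kmers()].
#' @param path file path.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(position = seq_len(nrow(logo$freq)), logo$freq,
                   IC_bits = logo$ic_bits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
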