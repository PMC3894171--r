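# Independent brute-force oracles used to pin down expected values. These
# deliberately share no code with the package implementations they check.

# Naive Hamming scan: every window of `sequence` within `m` mismatches of
# `pattern` (both plain ACGT strings; N never matches).
oracle_hamming_scan <- function(sequence, pattern, m) {
  sc <- strsplit(sequence, "")[[1L]]
  pc <- strsplit(pattern, "")[[1L]]
  k <- length(pc)
  if (length(sc) < k) {
    return(data.frame(start = integer(0L), mismatches = integer(0L)))
  }
  res <- lapply(seq_len(length(sc) - k + 1L), function(st) {
    win <- sc[st:(st + k - 1L)]
    mm <- sum(win != pc | win == "N")
    if (mm <= m) data.frame(start = st, mismatches = mm) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(start = integer(0L), mismatches = integer(0L))
  else out
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins: sum of probabilities <= observed probability
# (with the classical 1 + 1e-7 relative tolerance for ties).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b       # row 1 total
  n <- c + d       # row 2 total
  kk <- a + c      # column 1 total
  support <- max(0L, kk - n):min(kk, m)
  probs <- dhyper(support, m, n, kk)
  p_obs <- dhyper(a, m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Linear-scan empirical p-value with the add-one correction.
oracle_empirical_p <- function(score, null_scores) {
  (1 + sum(null_scores >= score)) / (length(null_scores) + 1)
}

# All 4^k k-mers over ACGT, as strings (k small).
oracle_all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

# One draw of a strictly positive random base distribution.
rdirichlet1 <- function() {
  g <- rgamma(4L, shape = 2) + 1e-3
  g / sum(g)
}

random_dna <- function(n, len, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1L))
}
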