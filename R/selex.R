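# Motif counting and enrichment statistics for selection (SELEX / GRO-RNA)
# read pools. A pool stores unique sequences with integer multiplicities and
# the total mapped-read normalizer used for MPM (multiplicity per million
# mapped reads).

#' Construct a read pool
#'
#' @param sequence character vector of unique sequences (canonicalized to
#'   the DNA alphabet; U becomes T).
#' @param multiplicity integer multiplicities, >= 1, same length.
#' @param total total mapped reads; defaults to `sum(multiplicity)` and may
#'   exceed it when unlisted reads exist.
#' @param label pool label.
#' @return object of class `read_pool`.
#' @export
read_pool <- function(sequence, multiplicity = rep(1L, length(sequence)),
                      total = sum(multiplicity), label = "pool") {
  sequence <- canonicalize_seq(sequence)
  if (anyDuplicated(sequence)) stop("sequences in a pool must be unique")
  multiplicity <- as.integer(multiplicity)
  if (length(multiplicity) != length(sequence) ||
      any(is.na(multiplicity)) || any(multiplicity < 1L)) {
    stop("multiplicities must be integers >= 1, one per sequence")
  }
  if (total < sum(multiplicity)) {
    stop("total cannot be smaller than the sum of listed multiplicities")
  }
  structure(list(sequence = sequence, multiplicity = multiplicity,
                 total = as.numeric(total), label = label),
            class = "read_pool")
}

#' @export
print.read_pool <- function(x, ...) {
  cat(sprintf("Read pool '%s': %d unique sequences, %s reads\n",
              x$label, length(x$sequence), format(x$total, big.mark = ",")))
  invisible(x)
}

#' Collapse a read stream into a pool by exact identity
#'
#' @param reads character vector of reads (one entry per read).
#' @param label pool label.
#' @return a `read_pool` with multiplicities from exact-identity collapse
#'   and `total` equal to the input read count. An empty stream yields an
#'   empty pool.
#' @export
dedupe_reads <- function(reads, label = "pool") {
  if (length(reads) == 0L) {
    return(structure(list(sequence = character(0L), multiplicity = integer(0L),
                          total = 0, label = label), class = "read_pool"))
  }
  reads <- canonicalize_seq(reads)
  tab <- table(reads)
  read_pool(names(tab), as.integer(tab), total = length(reads), label = label)
}

#' Top-n unique sequences by multiplicity
#'
#' Ties at the cutoff are broken lexicographically.
#'
#' @param pool a `read_pool`.
#' @param n number of sequences (>= 1).
#' @return character vector of up to `n` sequences, highest multiplicity
#'   first; if `n` exceeds the number of unique sequences, all are returned
#'   with a warning.
#' @export
top_n_by_multiplicity <- function(pool, n) {
  stopifnot(inherits(pool, "read_pool"), n >= 1L)
  ord <- order(-pool$multiplicity, pool$sequence)
  if (n > length(ord)) {
    warning("n exceeds the number of unique sequences; returning all ",
            length(ord))
    n <- length(ord)
  }
  pool$sequence[ord[seq_len(n)]]
}

#' Mismatch-tolerant motif matches within one sequence
#'
#' Reports every window whose Hamming distance to the pattern is at most
#' `max_mismatches`, in ascending start order; overlapping matches are all
#' reported. Ambiguous bases (N) never match any pattern base.
#'
#' @param sequence nucleotide string.
#' @param pattern motif string (U canonicalized to T).
#' @param max_mismatches mismatch budget, 0 <= m < pattern length
#'   (default 1, the budget used for NBE-like searches in read pools).
#' @return data.frame with columns `start` (1-based) and `mismatches`; zero
#'   rows when the sequence is shorter than the pattern or nothing matches.
#' @export
find_matches <- function(sequence, pattern, max_mismatches = 1L) {
  pat <- seq_to_int(canonicalize_seq(pattern, allow_ambiguous = FALSE))
  k <- length(pat)
  if (max_mismatches < 0L || max_mismatches >= k) {
    stop("max_mismatches must satisfy 0 <= m < pattern length")
  }
  s <- seq_to_int(canonicalize_seq(sequence))
  L <- length(s)
  if (L < k) {
    return(data.frame(start = integer(0L), mismatches = integer(0L)))
  }
  n_off <- L - k + 1L
  mm <- integer(n_off)
  for (i in seq_len(k)) {
    b <- s[i:(i + n_off - 1L)]
    mm <- mm + (is.na(b) | b != pat[i])   # N never matches
  }
  hit <- which(mm <= max_mismatches)
  data.frame(start = hit, mismatches = mm[hit])
}

# Vectorized full-overlap Hamming containment: TRUE for every sequence with
# at least one window within `m` mismatches of the (canonical, int-coded via
# seq_to_int) pattern. Sequences are processed in equal-length batches as
# int-code matrices, one column per sequence.
.pool_hits <- function(sequences, pattern, m) {
  pat <- seq_to_int(pattern)
  k <- length(pat)
  hits <- logical(length(sequences))
  lens <- nchar(sequences)
  for (L in unique(lens)) {
    if (L < k) next
    sel <- which(lens == L)
    mat <- matrix(.base_lut[utf8ToInt(paste(sequences[sel], collapse = ""))],
                  nrow = L)
    todo <- rep(TRUE, length(sel))
    for (o in seq_len(L - k + 1L)) {
      mm <- integer(length(sel))
      for (i in seq_len(k)) {
        b <- mat[o + i - 1L, ]
        mm <- mm + (is.na(b) | b != pat[i])
      }
      hit_o <- todo & mm <= m
      if (any(hit_o)) {
        hits[sel[hit_o]] <- TRUE
        todo <- todo & !hit_o
        if (!any(todo)) break
      }
    }
  }
  hits
}

#' Count motif-positive reads in a pool
#'
#' A read counts once no matter how many of its windows match; counts are
#' weighted by multiplicity. MPM = 1e6 x positive / total.
#'
#' @param pool a `read_pool`.
#' @param pattern motif string.
#' @param max_mismatches mismatch budget (default 1).
#' @return list with `positive_reads`, `total` and `mpm`.
#' @export
count_pool_matches <- function(pool, pattern, max_mismatches = 1L) {
  stopifnot(inherits(pool, "read_pool"))
  if (pool$total == 0) stop("MPM undefined: pool has zero total reads")
  pat <- canonicalize_seq(pattern, allow_ambiguous = FALSE)
  if (max_mismatches < 0L || max_mismatches >= nchar(pat)) {
    stop("max_mismatches must satisfy 0 <= m < pattern length")
  }
  if (length(pool$sequence) == 0L) {
    return(list(positive_reads = 0, total = pool$total, mpm = 0))
  }
  hits <- .pool_hits(pool$sequence, pat, max_mismatches)
  pos <- sum(pool$multiplicity[hits])
  list(positive_reads = pos, total = pool$total,
       mpm = 1e6 * pos / pool$total)
}

#' Motif enrichment between two pools by Fisher's exact test
#'
#' Builds the 2x2 table motif-positive/negative x target/control on
#' multiplicity-weighted read counts (or unique sequences) and tests
#' association with a two-sided Fisher exact test. The odds ratio is the
#' sample odds ratio ad/bc, with 0.5 added to every cell only when a zero
#' cell exists (flagged in the result).
#'
#' @param target,control `read_pool` objects.
#' @param pattern motif string.
#' @param max_mismatches mismatch budget (default 1).
#' @param unit count `"reads"` (multiplicity-weighted, default) or
#'   `"unique"` sequences.
#' @return class `enrichment_result`: list with the 2x2 `table`, per-pool
#'   `mpm`, `odds_ratio`, `continuity_corrected` flag and two-sided
#'   `p_value`.
#' @export
fisher_enrichment <- function(target, control, pattern, max_mismatches = 1L,
                              unit = c("reads", "unique")) {
  unit <- match.arg(unit)
  stopifnot(inherits(target, "read_pool"), inherits(control, "read_pool"))
  if (target$total == 0 || control$total == 0) {
    stop("both pools must have nonzero total reads")
  }
  count1 <- function(pool) {
    res <- count_pool_matches(pool, pattern, max_mismatches)
    if (unit == "unique") {
      hits <- .pool_hits(pool$sequence, canonicalize_seq(pattern),
                         max_mismatches)
      c(pos = sum(hits), tot = length(pool$sequence), mpm = res$mpm)
    } else {
      c(pos = res$positive_reads, tot = pool$total, mpm = res$mpm)
    }
  }
  tg <- count1(target)
  ct <- count1(control)
  tab <- matrix(c(tg["pos"], tg["tot"] - tg["pos"],
                  ct["pos"], ct["tot"] - ct["pos"]),
                nrow = 2L, byrow = TRUE,
                dimnames = list(pool = c(target$label, control$label),
                                motif = c("positive", "negative")))
  zero_cell <- any(tab == 0)
  tc <- if (zero_cell) tab + 0.5 else tab
  or <- (tc[1L, 1L] * tc[2L, 2L]) / (tc[1L, 2L] * tc[2L, 1L])
  p <- fisher.test(round(tab), alternative = "two.sided")$p.value
  structure(list(table = tab,
                 mpm = c(target = unname(tg["mpm"]),
                         control = unname(ct["mpm"])),
                 odds_ratio = unname(or),
                 continuity_corrected = zero_cell,
                 p_value = p, unit = unit),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Motif enrichment (Fisher exact, two-sided, unit =", x$unit, ")\n")
  print(x$table)
  cat(sprintf("  MPM target %.1f vs control %.1f; OR = %.3g%s; p = %.3g\n",
              x$mpm["target"], x$mpm["control"], x$odds_ratio,
              if (x$continuity_corrected) " (0.5 continuity)" else "",
              x$p_value))
  invisible(x)
}

#' Dominant k-mer among the top pool sequences
#'
#' Among the `top_n` highest-multiplicity unique sequences, finds the k-mer
#' present in the most sequences (presence, not occurrence count); ties go
#' to the lexicographically smallest k-mer. A desk-scale summarizer of the
#' dominant motif in a converged selection pool.
#'
#' @param pool a `read_pool`.
#' @param k k-mer length (>= 1).
#' @param top_n number of top sequences to summarize (default 3000).
#' @return list with `kmer` and `containing_fraction` (fraction of the
#'   examined sequences containing it).
#' @export
dominant_kmer <- function(pool, k, top_n = 3000L) {
  stopifnot(inherits(pool, "read_pool"), k >= 1L)
  top <- suppressWarnings(top_n_by_multiplicity(pool, top_n))
  top <- top[nchar(top) >= k]
  if (length(top) == 0L) stop("k is longer than every examined sequence")
  per_seq <- lapply(top, function(s) {
    n_off <- nchar(s) - k + 1L
    unique(substring(s, seq_len(n_off), seq_len(n_off) + k - 1L))
  })
  tab <- table(unlist(per_seq, use.names = FALSE))
  # exclude k-mers containing ambiguous bases
  tab <- tab[!grepl("N", names(tab), fixed = TRUE)]
  if (length(tab) == 0L) stop("no unambiguous k-mer found")
  best <- sort(names(tab[tab == max(tab)]))[1L]  # lexicographic tie-break
  list(kmer = best,
       containing_fraction = as.numeric(max(tab)) / length(top))
}

#' Write / read a pre-collapsed pool as TSV (sequence, multiplicity)
#'
#' The total is carried in a header comment so pools whose total exceeds the
#' listed multiplicities round-trip losslessly.
#'
#' @param pool a `read_pool`.
#' @param path file path.
#' @return `read_pool_tsv` returns the reconstructed `read_pool`.
#' @export
write_pool_tsv <- function(pool, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# label=%s total=%.17g", pool$label, pool$total), con)
  write.table(data.frame(sequence = pool$sequence,
                         multiplicity = pool$multiplicity),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
read_pool_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("label=(\\S+) total=(\\S+)", hdr))[[1L]]
  if (length(m) != 3L) stop("malformed pool TSV header: ", path)
  df <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  read_pool(df$sequence, df$multiplicity, total = as.numeric(m[3L]),
            label = m[2L])
}

#' Per-position single-mismatch motif counts in a pool
#'
#' Splits motif-positive reads by where their single mismatch falls: reads
#' containing an exact motif match are counted under `"exact"`; a read with
#' no exact match is counted under position i if some window matches with
#' its single mismatch at pattern position i (a read can satisfy this for
#' more than one position and then appears in each such row).
#'
#' @param pool a `read_pool`.
#' @param pattern motif string.
#' @return data.frame with `category` ("exact" or "pos<i>"), `reads`
#'   (multiplicity-weighted) and `mpm`.
#' @export
position_variant_counts <- function(pool, pattern) {
  stopifnot(inherits(pool, "read_pool"))
  if (pool$total == 0) stop("MPM undefined: pool has zero total reads")
  pat <- canonicalize_seq(pattern, allow_ambiguous = FALSE)
  k <- nchar(pat)
  pat_int <- seq_to_int(pat)
  cats <- c("exact", paste0("pos", seq_len(k)))
  reads <- setNames(numeric(length(cats)), cats)
  for (j in seq_along(pool$sequence)) {
    m <- find_matches(pool$sequence[j], pat, max_mismatches = 1L)
    if (nrow(m) == 0L) next
    w <- pool$multiplicity[j]
    if (any(m$mismatches == 0L)) {
      reads["exact"] <- reads["exact"] + w
    } else {
      s_int <- seq_to_int(pool$sequence[j])
      pos_hit <- unique(unlist(lapply(m$start, function(st) {
        b <- s_int[st:(st + k - 1L)]
        which(is.na(b) | b != pat_int)
      })))
      reads[paste0("pos", pos_hit)] <- reads[paste0("pos", pos_hit)] + w
    }
  }
  data.frame(category = cats, reads = unname(reads),
             mpm = 1e6 * unname(reads) / pool$total)
}
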