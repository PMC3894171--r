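# Promoter-proximal PWM scanning with a permutation null.
#
# Conventions (fixed across the package): promoter windows are TSS-anchored
# on the sense strand, offset 0 = the first transcribed base, default span
# -50..+150 inclusive (201 bases); a k-mer is assigned the offset of its
# 5'-most base, so the scanned offsets run -50..+(150 - k + 1).

.check_windows <- function(windows) {
  if (!is.data.frame(windows) ||
      !all(c("gene_id", "sequence") %in% names(windows))) {
    stop("windows must be a data.frame with columns gene_id and sequence")
  }
  if (nrow(windows) == 0L) stop("windows must be non-empty")
  if (anyDuplicated(windows$gene_id)) stop("gene_id values must be unique")
  invisible(windows)
}

#' Build a permutation null score distribution
#'
#' Draws `n` k-mers from the observed promoter windows under a permutation
#' scheme and scores them with the PWM, giving the null distribution against
#' which scanned scores are converted to empirical p-values.
#'
#' Schemes: `"permute_window"` (default) samples a window uniformly, permutes
#' its letters uniformly at random and reads a k-mer at a uniform offset --
#' equivalently, draws k letters without replacement from the window -- so
#' each draw preserves that window's base composition. `"permute_kmer"`
#' shuffles the letters of an observed k-mer in place (uniform window and
#' offset). Ambiguous bases are excluded from draws.
#'
#' @param windows data.frame with columns `gene_id`, `sequence`.
#' @param pwm an `nbe_pwm` from [build_pwm()].
#' @param n number of null draws (>= 1000; the full-scale analysis uses
#'   100000).
#' @param seed integer seed; the draw is a pure function of
#'   (windows, pwm, n, seed, scheme).
#' @param scheme permutation scheme, see Details.
#' @return an object of class `nbe_null`: list with sorted `scores`, `n`,
#'   `scheme` and `seed`.
#' @export
build_null <- function(windows, pwm, n = 1e5, seed = 1L,
                       scheme = c("permute_window", "permute_kmer")) {
  .check_windows(windows)
  scheme <- match.arg(scheme)
  n <- as.integer(n)
  if (n < 1000L) stop("n must be at least 1000")
  k <- motif_length(pwm)

  ints <- lapply(windows$sequence,
                 function(s) seq_to_int(canonicalize_seq(s)))
  if (scheme == "permute_window") {
    # drawing k letters without replacement from the (NA-stripped) window is
    # exactly a uniform whole-window permutation read at a uniform offset
    ints <- lapply(ints, function(v) v[!is.na(v)])
    usable <- lengths(ints) >= k
  } else {
    usable <- lengths(ints) >= k
  }
  if (!any(usable)) stop("no window long enough for the motif")
  ints <- ints[usable]

  scores <- withr::with_seed(seed, {
    out <- numeric(n)
    filled <- 0L
    while (filled < n) {
      need <- n - filled
      wi <- sample.int(length(ints), need, replace = TRUE)
      draw <- vapply(wi, function(j) {
        v <- ints[[j]]
        if (scheme == "permute_window") {
          km <- v[sample.int(length(v), k)]
        } else {
          o <- sample.int(length(v) - k + 1L, 1L)
          km <- sample(v[o:(o + k - 1L)])
        }
        if (anyNA(km)) return(NA_real_)
        .score_kmer_ints(pwm, km)
      }, numeric(1L))
      draw <- draw[!is.na(draw)]
      if (length(draw)) {
        out[(filled + 1L):(filled + length(draw))] <- draw
        filled <- filled + length(draw)
      }
    }
    out
  })
  structure(list(scores = sort(scores), n = n, scheme = scheme, seed = seed),
            class = "nbe_null")
}

#' @export
print.nbe_null <- function(x, ...) {
  cat(sprintf("Permutation null: %d scores (%s, seed %d), range [%.3f, %.3f]\n",
              x$n, x$scheme, x$seed, x$scores[1L], x$scores[x$n]))
  invisible(x)
}

#' Empirical p-value of a score against a permutation null
#'
#' Default (`ties = "count"`) is the add-one count
#' p = (1 + #\{null >= score\}) / (N + 1), which is strictly positive (so
#' -log10 p is finite) and conservative (super-uniform) when the score
#' distribution is discrete. `ties = "randomized"` applies the standard
#' randomized construction p = (#\{null > score\} + U (1 + #\{null = score\}))
#' / (N + 1), U ~ Uniform(0,1), which is exactly Uniform(0,1) when the score
#' is drawn from the null -- the right variant for calibration checks.
#'
#' @param score numeric vector of observed scores (NA passes through).
#' @param null an `nbe_null` from [build_null()].
#' @param ties `"count"` (default) or `"randomized"`.
#' @return numeric vector of p-values in (0, 1].
#' @export
empirical_pvalue <- function(score, null, ties = c("count", "randomized")) {
  ties <- match.arg(ties)
  stopifnot(inherits(null, "nbe_null"))
  s <- null$scores
  n <- null$n
  ge <- n - findInterval(score, s, left.open = TRUE)  # null >= score
  if (ties == "count") {
    p <- (1 + ge) / (n + 1)
  } else {
    gt <- n - findInterval(score, s)                  # null >  score
    p <- (gt + runif(length(score)) * (1 + ge - gt)) / (n + 1)
  }
  p[!is.finite(score)] <- NA_real_
  p
}

#' Scan promoter windows and convert scores to similarity indices
#'
#' Scores every k-mer on the sense strand of each window, converts scores to
#' empirical p-values against the permutation null, and reports the
#' similarity index -log10(p) (the quantity mapped in promoter heat maps).
#'
#' @param windows data.frame with columns `gene_id`, `sequence` and
#'   optionally `group`.
#' @param pwm an `nbe_pwm`.
#' @param null an `nbe_null` built with the same PWM.
#' @param window_start TSS-relative offset of the first window base
#'   (default -50).
#' @return class `nbe_tracks`: long data.frame with columns `gene_id`,
#'   `offset`, `score`, `p_value`, `similarity_index` (NA at unscoreable
#'   offsets), with attributes `k` and `window_start`.
#' @export
scan_windows <- function(windows, pwm, null, window_start = -50L) {
  .check_windows(windows)
  stopifnot(inherits(null, "nbe_null"))
  k <- motif_length(pwm)
  keep <- nchar(windows$sequence) >= k
  if (!all(keep)) {
    warning(sum(!keep), " window(s) shorter than the motif were skipped")
    windows <- windows[keep, , drop = FALSE]
    if (nrow(windows) == 0L) stop("no scannable windows")
  }
  per_gene <- lapply(seq_len(nrow(windows)), function(i) {
    sc <- score_offsets_int(seq_to_int(canonicalize_seq(windows$sequence[i])),
                            pwm)
    data.frame(gene_id = windows$gene_id[i],
               offset = window_start + seq_along(sc) - 1L,
               score = sc)
  })
  tracks <- do.call(rbind, per_gene)
  tracks$p_value <- empirical_pvalue(tracks$score, null)
  tracks$similarity_index <- -log10(tracks$p_value)
  attr(tracks, "k") <- k
  attr(tracks, "window_start") <- as.integer(window_start)
  class(tracks) <- c("nbe_tracks", "data.frame")
  tracks
}

# Per-gene maximum similarity index within a TSS-relative offset interval.
# Genes whose region is entirely unscoreable are dropped.
.gene_test_values <- function(tracks, region, column = "similarity_index") {
  stopifnot(inherits(tracks, "nbe_tracks"), length(region) == 2L)
  sub <- tracks[tracks$offset >= region[1L] & tracks$offset <= region[2L] &
                  !is.na(tracks[[column]]), , drop = FALSE]
  if (nrow(sub) == 0L) return(setNames(numeric(0L), character(0L)))
  vals <- tapply(sub[[column]], sub$gene_id, max)
  setNames(as.numeric(vals), names(vals))
}

#' Best-matching k-mer per gene within a region
#'
#' Returns, for each gene, the k-mer at the maximal raw PWM score within the
#' region (default +0..+50), breaking ties toward the 5'-most offset. The
#' result feeds [logo_from_kmers()] for the genomic motif logo.
#'
#' @param tracks an `nbe_tracks` from [scan_windows()].
#' @param windows the windows the tracks were computed from.
#' @param region length-2 TSS-relative offset interval, inclusive.
#' @return named character vector of k-mers (names = gene ids); genes whose
#'   region is entirely unscoreable are omitted with a warning.
#' @export
best_match_per_gene <- function(tracks, windows, region = c(0L, 50L)) {
  .check_windows(windows)
  k <- attr(tracks, "k")
  window_start <- attr(tracks, "window_start")
  sub <- tracks[tracks$offset >= region[1L] & tracks$offset <= region[2L] &
                  !is.na(tracks$score), , drop = FALSE]
  sub_split <- split(sub[, c("offset", "score")], sub$gene_id)
  best <- vapply(as.character(windows$gene_id), function(g) {
    tg <- sub_split[[g]]
    if (is.null(tg) || nrow(tg) == 0L) return(NA_integer_)
    tg$offset[which.max(tg$score)]  # which.max takes the first (5'-most) tie
  }, integer(1L))
  omitted <- is.na(best)
  if (any(omitted)) {
    warning(sum(omitted), " gene(s) had no scoreable k-mer in the region ",
            "and were omitted")
  }
  seqs <- canonicalize_seq(windows$sequence)
  kmers <- substr(seqs, best - window_start + 1L, best - window_start + k)
  setNames(kmers, windows$gene_id)[!omitted]
}

#' Average similarity-index profile across genes
#'
#' @param tracks an `nbe_tracks`.
#' @return data.frame with `offset`, `mean_index` (mean over genes with a
#'   scoreable k-mer at that offset) and `n_genes`.
#' @export
average_profile <- function(tracks) {
  stopifnot(inherits(tracks, "nbe_tracks"), nrow(tracks) > 0L)
  ok <- !is.na(tracks$similarity_index)
  mean_idx <- tapply(tracks$similarity_index[ok], tracks$offset[ok], mean)
  n <- tapply(tracks$similarity_index[ok], tracks$offset[ok], length)
  data.frame(offset = as.integer(names(mean_idx)),
             mean_index = as.numeric(mean_idx),
             n_genes = as.integer(n),
             row.names = NULL)
}

#' Compare pausing groups by promoter-proximal motif similarity
#'
#' Each gene's test value is its maximum similarity index within `region`
#' (default +10..+30, the promoter-proximal pause band). The two groups are
#' compared with a two-sided two-sample Kolmogorov-Smirnov test and a Welch
#' unequal-variance t-test.
#'
#' @param tracks an `nbe_tracks`.
#' @param groups group labels: either a named character vector (names =
#'   gene ids) or a data.frame with columns `gene_id`, `group`. Exactly two
#'   distinct labels are required.
#' @param region length-2 offset interval, inclusive.
#' @return class `nbe_group_comparison`: list with `test_values` (list of two
#'   named numeric vectors), `n` (group sizes), `ks_statistic`, `ks_p`,
#'   `welch_t_p`, and `reason` (non-NULL when the tests are undefined).
#' @export
compare_groups <- function(tracks, groups, region = c(10L, 30L)) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$gene_id)
  }
  vals <- .gene_test_values(tracks, region)
  grp <- groups[names(vals)]
  vals <- vals[!is.na(grp)]
  grp <- grp[!is.na(grp)]
  labels <- sort(unique(grp))
  if (length(labels) != 2L) stop("exactly two group labels are required")
  split_vals <- split(vals, factor(grp, levels = labels))
  n <- vapply(split_vals, length, integer(1L))
  res <- list(test_values = split_vals, n = n, region = region,
              ks_statistic = NA_real_, ks_p = NA_real_,
              welch_t_p = NA_real_, reason = NULL)
  if (any(n < 2L)) {
    res$reason <- "each group needs at least 2 genes with scoreable regions"
  } else {
    ks <- suppressWarnings(ks.test(split_vals[[1L]], split_vals[[2L]],
                                   alternative = "two.sided"))
    tt <- t.test(split_vals[[1L]], split_vals[[2L]], var.equal = FALSE)
    res$ks_statistic <- unname(ks$statistic)
    res$ks_p <- ks$p.value
    res$welch_t_p <- tt$p.value
  }
  class(res) <- "nbe_group_comparison"
  res
}

#' @export
print.nbe_group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of max similarity index in +%d..+%d\n",
              x$region[1L], x$region[2L]))
  cat(sprintf("  groups: %s (n = %s)\n",
              paste(names(x$test_values), collapse = " vs "),
              paste(x$n, collapse = ", ")))
  if (!is.null(x$reason)) {
    cat("  tests undefined:", x$reason, "\n")
  } else {
    cat(sprintf("  KS D = %.4f, p = %.3g; Welch t p = %.3g\n",
                x$ks_statistic, x$ks_p, x$welch_t_p))
  }
  invisible(x)
}

#' Gene-by-offset similarity matrix for heat maps
#'
#' @param tracks an `nbe_tracks`.
#' @param order `"by_max_index"` (rows sorted by descending maximum
#'   similarity index within `region`) or `"input"`.
#' @param region ordering region, default +10..+30.
#' @return numeric matrix (genes x offsets) of similarity indices with NA at
#'   unscoreable offsets; rownames = gene ids, colnames = offsets.
#' @export
heatmap_matrix <- function(tracks, order = c("by_max_index", "input"),
                           region = c(10L, 30L)) {
  order <- match.arg(order)
  stopifnot(inherits(tracks, "nbe_tracks"))
  genes <- unique(tracks$gene_id)
  offsets <- sort(unique(tracks$offset))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(offsets),
                dimnames = list(genes, offsets))
  mat[cbind(match(tracks$gene_id, genes), match(tracks$offset, offsets))] <-
    tracks$similarity_index
  if (order == "by_max_index") {
    strength <- .gene_test_values(tracks, region)
    key <- strength[genes]
    key[is.na(key)] <- -Inf
    mat <- mat[order(key, decreasing = TRUE), , drop = FALSE]
  }
  mat
}

#' Positional distributions of the similarity index near the TSS
#'
#' For each center c, collects the per-gene maximum similarity index within
#' c +/- halfwidth and runs Welch t-tests between adjacent centers.
#'
#' @param tracks an `nbe_tracks`.
#' @param centers TSS-relative offsets (default 0, 10, 20, 30, 40).
#' @param halfwidth half-window in bases (default 5; 0 gives single-offset
#'   values).
#' @return list with `values` (named list of per-gene vectors, one per
#'   center) and `adjacent_tests` (data.frame `center_a`, `center_b`,
#'   `welch_t_p`).
#' @export
positional_boxplot_stats <- function(tracks, centers = seq(0L, 40L, 10L),
                                     halfwidth = 5L) {
  vals <- lapply(centers, function(ctr) {
    .gene_test_values(tracks, c(ctr - halfwidth, ctr + halfwidth))
  })
  names(vals) <- as.character(centers)
  adj <- NULL
  if (length(centers) > 1L) {
    adj <- data.frame(center_a = centers[-length(centers)],
                      center_b = centers[-1L],
                      welch_t_p = NA_real_)
    for (i in seq_len(nrow(adj))) {
      a <- vals[[i]]; b <- vals[[i + 1L]]
      if (length(a) >= 2L && length(b) >= 2L) {
        if (identical(unname(a), unname(b))) {
          adj$welch_t_p[i] <- 1
        } else {
          adj$welch_t_p[i] <- t.test(a, b, var.equal = FALSE)$p.value
        }
      }
    }
  }
  list(values = vals, adjacent_tests = adj)
}
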