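# Small fixed fixtures: windows are built in code so every expected value is
# derivable by hand or by the oracles in helper-oracles.R.

make_uniform_pwm <- function() build_pwm("CUGAGGA", 0.85)

test_that("scanning an all-A window gives the closed-form flat track", {
  pwm <- make_uniform_pwm()
  win <- data.frame(gene_id = "g1",
                    sequence = strrep("A", 201L))
  null <- build_null(win, pwm, n = 1000, seed = 1)
  tr <- scan_windows(win, pwm, null)
  expect_equal(nrow(tr), 201L - 7L + 1L)
  expect_equal(tr$offset, -50:144)
  # all-A 7-mer: positions 4 and 7 of CTGAGGA match A, the rest mismatch
  exp_score <- 2 * log2(0.85 / 0.25) + 5 * log2(0.05 / 0.25)
  expect_true(all(abs(tr$score - exp_score) < 1e-12))
  # degenerate null: every null score equals the observed -> p = 1
  expect_true(all(tr$p_value == 1))
  expect_true(all(tr$similarity_index == 0))
})

test_that("a planted consensus is the track argmax at its offset", {
  pwm <- make_uniform_pwm()
  set.seed(11)
  base <- random_dna(1L, 201L)
  # avoid accidental high-scoring background: plant into a low-score window
  seq1 <- paste0(substr(base, 1L, 75L), "CTGAGGA", substr(base, 83L, 201L))
  win <- data.frame(gene_id = "g1", sequence = seq1)
  null <- build_null(win, pwm, n = 1000, seed = 2)
  tr <- scan_windows(win, pwm, null)
  expect_equal(tr$offset[which.max(tr$score)], 25L)  # 76th base = offset +25
  # determinism: identical windows give identical tracks
  tr2 <- scan_windows(win, pwm, null)
  expect_identical(tr, tr2)
})

test_that("ambiguous bases mark windows unscoreable and short windows skip", {
  pwm <- make_uniform_pwm()
  win <- data.frame(gene_id = c("g1", "g2"),
                    sequence = c(paste0(strrep("A", 20L), "N",
                                        strrep("A", 20L)),
                                 "ACGT"))
  null <- build_null(win, pwm, n = 1000, seed = 3)
  expect_warning(tr <- scan_windows(win, pwm, null, window_start = 0L),
                 "skipped")
  expect_equal(unique(tr$gene_id), "g1")
  # windows overlapping the N at position 21 are NA
  na_off <- tr$offset[is.na(tr$score)]
  expect_equal(na_off, 14:20)
})

test_that("empirical p-values match the linear-scan oracle and its bounds", {
  set.seed(5)
  null_scores <- rnorm(5000)
  null <- structure(list(scores = sort(null_scores), n = 5000L,
                         scheme = "permute_window", seed = 5L),
                    class = "nbe_null")
  probe <- c(rnorm(200), null_scores[1:50],
             min(null_scores) - 1, max(null_scores) + 1)
  p <- empirical_pvalue(probe, null)
  p_oracle <- vapply(probe, oracle_empirical_p, numeric(1L), null_scores)
  expect_equal(p, p_oracle)
  expect_true(all(p >= 1 / 5001 & p <= 1))
  expect_equal(empirical_pvalue(min(null_scores) - 1, null), 1)
  expect_equal(empirical_pvalue(max(null_scores) + 1, null), 1 / 5001)
  # score at the median of an odd-sized null has p ~ 0.5
  nullo <- structure(list(scores = sort(rnorm(4999)), n = 4999L,
                          scheme = "permute_window", seed = 1L),
                     class = "nbe_null")
  expect_equal(empirical_pvalue(nullo$scores[2500], nullo),
               oracle_empirical_p(nullo$scores[2500], nullo$scores))
  expect_equal(empirical_pvalue(nullo$scores[2500], nullo), 2501 / 5000)
})

test_that("score monotonicity implies p monotone and index monotone", {
  set.seed(6)
  null <- structure(list(scores = sort(rnorm(2000)), n = 2000L,
                         scheme = "permute_window", seed = 6L),
                    class = "nbe_null")
  s <- sort(rnorm(100))
  p <- empirical_pvalue(s, null)
  expect_true(all(diff(p) <= 0))
  expect_true(all(diff(-log10(p)) >= 0))
})

test_that("the permutation null preserves composition and is reproducible", {
  pwm <- make_uniform_pwm()
  # single pure-A window: every null draw must score the all-A k-mer
  win_a <- data.frame(gene_id = "g1", sequence = strrep("A", 60L))
  null_a <- build_null(win_a, pwm, n = 1000, seed = 9)
  expect_equal(length(unique(null_a$scores)), 1L)
  expect_equal(null_a$scores[1L],
               2 * log2(0.85 / 0.25) + 5 * log2(0.05 / 0.25),
               tolerance = 1e-12)

  set.seed(20)
  win <- data.frame(gene_id = paste0("g", 1:5),
                    sequence = random_dna(5L, 201L))
  n1 <- build_null(win, pwm, n = 1000, seed = 10)
  n2 <- build_null(win, pwm, n = 1000, seed = 10)
  expect_identical(n1, n2)
  n3 <- build_null(win, pwm, n = 1000, seed = 11)
  expect_false(identical(n1$scores, n3$scores))
  # both schemes accepted
  n4 <- build_null(win, pwm, n = 1000, seed = 10, scheme = "permute_kmer")
  expect_equal(n4$scheme, "permute_kmer")
  expect_error(build_null(win, pwm, n = 100, seed = 1), "at least 1000")
})

test_that("best_match_per_gene returns the maximal k-mer with 5'-most ties", {
  pwm <- make_uniform_pwm()
  low <- strrep("T", 30L)  # TTTTTTT scores 1 match (position 2)
  # plant one perfect site
  s1 <- paste0(low, "CTGAGGA", low, strrep("T", 134L))
  # plant the same perfect site twice: tie broken toward the 5'-most
  s2 <- paste0(low, "CTGAGGA", strrep("T", 10L), "CTGAGGA",
               strrep("T", 117L))
  win <- data.frame(gene_id = c("g1", "g2"), sequence = c(s1, s2))
  null <- build_null(win, pwm, n = 1000, seed = 4)
  tr <- scan_windows(win, pwm, null, window_start = 0L)
  bm <- best_match_per_gene(tr, win, region = c(0L, 60L))
  expect_equal(unname(bm), c("CTGAGGA", "CTGAGGA"))
  # 5'-most rule: re-scan g2 and confirm argmax offset is the first plant
  tr2 <- tr[tr$gene_id == "g2" & !is.na(tr$score), ]
  expect_equal(tr2$offset[which.max(tr2$score)], 30L)

  # all-A window: best match is AAAAAAA
  win3 <- data.frame(gene_id = "g3", sequence = strrep("A", 60L))
  null3 <- build_null(win3, pwm, n = 1000, seed = 5)
  tr3 <- scan_windows(win3, pwm, null3, window_start = 0L)
  expect_equal(unname(best_match_per_gene(tr3, win3, region = c(0L, 40L))),
               "AAAAAAA")
})

test_that("average_profile is the identity for one track and handles NA", {
  pwm <- make_uniform_pwm()
  win <- data.frame(gene_id = "g1",
                    sequence = paste0(strrep("A", 40L), "N",
                                      strrep("A", 160L)))
  null <- build_null(win, pwm, n = 1000, seed = 6)
  tr <- scan_windows(win, pwm, null)
  prof <- average_profile(tr)
  ok <- !is.na(tr$similarity_index)
  expect_equal(prof$mean_index, tr$similarity_index[ok])
  expect_equal(prof$offset, tr$offset[ok])
  expect_true(all(prof$n_genes == 1L))
})

test_that("group comparison is symmetric and degenerate groups are flagged", {
  pwm <- make_uniform_pwm()
  set.seed(30)
  win <- data.frame(gene_id = paste0("g", 1:8),
                    sequence = random_dna(8L, 201L))
  null <- build_null(win, pwm, n = 1000, seed = 7)
  tr <- scan_windows(win, pwm, null)

  # identical groups: copy the same four genes into both labels
  tr_dup <- tr
  tr_dup$gene_id <- paste0(tr_dup$gene_id, "_b")
  both <- rbind(tr, tr_dup)
  attributes(both)[c("k", "window_start", "class")] <-
    attributes(tr)[c("k", "window_start", "class")]
  groups <- c(setNames(rep("x", 8L), paste0("g", 1:8)),
              setNames(rep("y", 8L), paste0("g", 1:8, "_b")))
  cg <- compare_groups(both, groups)
  expect_equal(cg$ks_statistic, 0)
  expect_equal(cg$ks_p, 1)

  # label swap leaves two-sided p-values unchanged
  groups_sw <- setNames(ifelse(groups == "x", "y", "x"), names(groups))
  cg_sw <- compare_groups(both, groups_sw)
  expect_equal(cg$ks_p, cg_sw$ks_p)
  expect_equal(cg$welch_t_p, cg_sw$welch_t_p)

  # a group of size < 2 reports a reason instead of statistics
  small <- compare_groups(tr, setNames(c("x", rep("y", 7L)),
                                       paste0("g", 1:8)))
  expect_false(is.null(small$reason))
  expect_true(is.na(small$ks_p))
  expect_error(compare_groups(tr, setNames(rep("x", 8L), paste0("g", 1:8))),
               "two group labels")
})

test_that("heatmap matrix has scan geometry and requested row order", {
  pwm <- make_uniform_pwm()
  set.seed(33)
  win <- data.frame(gene_id = sprintf("g%02d", 1:12),
                    sequence = random_dna(12L, 201L))
  null <- build_null(win, pwm, n = 2000, seed = 8)
  tr <- scan_windows(win, pwm, null)
  mat <- heatmap_matrix(tr, order = "by_max_index", region = c(10L, 30L))
  expect_equal(dim(mat), c(12L, 195L))
  expect_equal(colnames(mat), as.character(-50:144))
  # independently recompute the ordering key (stable on ties, descending)
  region_cols <- as.character(10:30)
  key <- apply(mat[win$gene_id, region_cols], 1L, max, na.rm = TRUE)
  expect_equal(rownames(mat),
               win$gene_id[order(key, decreasing = TRUE)])
  expect_true(all(diff(apply(mat[, region_cols], 1L, max,
                             na.rm = TRUE)) <= 0))
  mat_in <- heatmap_matrix(tr, order = "input")
  expect_equal(rownames(mat_in), win$gene_id)
  # matrix values are exactly the track similarity indices
  expect_equal(unname(mat_in["g03", "25"]),
               tr$similarity_index[tr$gene_id == "g03" & tr$offset == 25L])
})

test_that("positional stats recover a planted band and degenerate cases", {
  sim <- simulate_promoters(promoter_sim_config(
    n_per_group = c(paused = 150L),
    embed_prob = c(paused = 1),
    mutation_rate = 0, offset_mean = 25, offset_sd = 0, seed = 31))
  pwm <- build_pwm("CUGAGGA", 0.85, background = sim$config$background)
  null <- build_null(sim$windows, pwm, n = 2000, seed = 32)
  tr <- scan_windows(sim$windows, pwm, null)
  pb <- positional_boxplot_stats(tr)
  med <- vapply(pb$values, median, numeric(1L))
  expect_true(all(med[c("20", "30")] >= med[c("0", "40")]))
  expect_gt(min(med[c("20", "30")]), max(med[c("0", "10", "40")]) - 1e-9)

  # halfwidth 0 reduces to single-offset values
  pb0 <- positional_boxplot_stats(tr, centers = 25L, halfwidth = 0L)
  v25 <- tr$similarity_index[tr$offset == 25L]
  expect_equal(sort(unname(pb0$values[["25"]])), sort(v25[!is.na(v25)]))

  # identical bins give p = 1
  pb_same <- positional_boxplot_stats(tr, centers = c(25L, 25L),
                                      halfwidth = 3L)
  expect_equal(pb_same$adjacent_tests$welch_t_p, 1)
})

test_that("group separation grows with the embedding-probability gap", {
  pwm <- build_pwm("CUGAGGA", 0.85,
                   background = c(A = 0.29, C = 0.205, G = 0.235, T = 0.27))
  stat_for_gap <- function(p_paused) {
    sim <- simulate_promoters(promoter_sim_config(
      n_per_group = c(paused = 120L, non_paused = 120L),
      embed_prob = c(paused = p_paused, non_paused = 0.1),
      seed = 71L))
    null <- build_null(sim$windows, pwm, n = 2000, seed = 72L)
    tr <- scan_windows(sim$windows, pwm, null)
    compare_groups(tr, sim$windows[, c("gene_id", "group")])$ks_statistic
  }
  d <- vapply(c(0.1, 0.35, 0.6), stat_for_gap, numeric(1L))
  expect_true(all(diff(d) > 0))
})
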