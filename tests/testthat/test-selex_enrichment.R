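tar_seq <- "GGUCUCUCUGGUUAGACCAGAUCUGAGCCUGGGAGCUCUCUGGCUAACUAGGGAACC"
tar_a_seq <- "GGUCUCUCUGGUUAGACCAGAUCUGAGCCUGAGGAGCUCUCUGGCUAACUAGGGAACC"

test_that("exact motif search on the TAR loop variants", {
  m_a <- find_matches(tar_a_seq, "CUGAGGA", max_mismatches = 0L)
  expect_equal(m_a$start, 29L)
  expect_equal(m_a$mismatches, 0L)
  m_wt <- find_matches(tar_seq, "CUGAGGA", max_mismatches = 0L)
  expect_equal(nrow(m_wt), 0L)
  # the wild-type loop element CUGGGA relates to the consensus by a
  # deletion, not a substitution, so even one allowed mismatch finds nothing
  m_wt1 <- find_matches(tar_seq, "CUGAGGA", max_mismatches = 1L)
  expect_equal(nrow(m_wt1), 0L)
  # pattern equal to the full sequence
  self <- find_matches("CUGAGGA", "CUGAGGA", max_mismatches = 0L)
  expect_equal(self$start, 1L)
  # too-short sequence gives an empty result
  expect_equal(nrow(find_matches("CUG", "CUGAGGA")), 0L)
  expect_error(find_matches(tar_seq, "CUGAGGA", max_mismatches = 7L),
               "max_mismatches")
})

test_that("find_matches equals the brute-force Hamming oracle", {
  set.seed(13)
  for (case in 1:300) {
    sq <- random_dna(1L, sample(7:60, 1L))
    pat <- random_dna(1L, sample(3:7, 1L))
    m <- sample(0:(nchar(pat) - 1L), 1L)
    got <- find_matches(sq, pat, m)
    want <- oracle_hamming_scan(sq, pat, m)
    expect_equal(got$start, want$start)
    expect_equal(got$mismatches, want$mismatches)
  }
  # ambiguous bases never match
  expect_equal(nrow(find_matches("CUGANGA", "CUGAGGA",
                                 max_mismatches = 0L)), 0L)
  expect_equal(find_matches("CUGANGA", "CUGAGGA",
                            max_mismatches = 1L)$mismatches, 1L)
})

test_that("dedupe collapses by exact identity, order-invariantly", {
  pool <- dedupe_reads(c("AAA", "AAA", "CCC"))
  expect_equal(pool$sequence, c("AAA", "CCC"))
  expect_equal(pool$multiplicity, c(2L, 1L))
  expect_equal(pool$total, 3)

  shuffled <- dedupe_reads(c("CCC", "AAA", "AAA"))
  expect_equal(shuffled$sequence, pool$sequence)
  expect_equal(shuffled$multiplicity, pool$multiplicity)

  uniq <- dedupe_reads(c("GGG", "TTT"))
  expect_true(all(uniq$multiplicity == 1L))

  empty <- dedupe_reads(character(0L))
  expect_equal(length(empty$sequence), 0L)
  expect_equal(empty$total, 0)
})

test_that("top-n selection is multiplicity-ordered with lexicographic ties", {
  pool <- read_pool(c("TTT", "AAA", "CCC"), c(5L, 3L, 1L))
  expect_equal(top_n_by_multiplicity(pool, 2L), c("TTT", "AAA"))
  # tie at the cutoff: lexicographic order decides
  pool_tie <- read_pool(c("TTT", "GGG", "AAA"), c(5L, 3L, 3L))
  expect_equal(top_n_by_multiplicity(pool_tie, 2L), c("TTT", "AAA"))
  expect_warning(all_of <- top_n_by_multiplicity(pool, 10L), "exceeds")
  expect_equal(length(all_of), 3L)
})

test_that("pool counting weights by multiplicity and normalizes to MPM", {
  pool <- read_pool(c("AACUGAGGAUU", "GGGGGGGGGGG"), c(1L, 9L))
  res <- count_pool_matches(pool, "CUGAGGA", max_mismatches = 0L)
  expect_equal(res$positive_reads, 1)
  expect_equal(res$mpm, 1e5)
  # a read counts once regardless of how many windows match
  pool2 <- read_pool("CUGAGGACUGAGGA", 2L)
  expect_equal(count_pool_matches(pool2, "CUGAGGA", 0L)$positive_reads, 2)
  # doubling multiplicities leaves MPM unchanged
  pool_x2 <- read_pool(pool$sequence, pool$multiplicity * 2L)
  expect_equal(count_pool_matches(pool_x2, "CUGAGGA", 0L)$mpm, res$mpm)
  # mismatch budget is monotone
  m0 <- count_pool_matches(pool, "CUGAGGA", 0L)$positive_reads
  m1 <- count_pool_matches(pool, "CUGAGGA", 1L)$positive_reads
  expect_gte(m1, m0)
  # agreement with find_matches on random pools
  set.seed(14)
  rp <- dedupe_reads(random_dna(200L, 30L))
  for (m in 0:2) {
    got <- count_pool_matches(rp, "CUGAGGA", m)$positive_reads
    want <- sum(rp$multiplicity[vapply(rp$sequence, function(s) {
      nrow(find_matches(s, "CUGAGGA", m)) > 0L
    }, logical(1L))])
    expect_equal(got, want)
  }
  empty <- dedupe_reads(character(0L))
  expect_error(count_pool_matches(empty, "CUGAGGA"), "zero total")
})

test_that("Fisher enrichment matches the hypergeometric enumeration oracle", {
  mk_pool <- function(pos, neg, label) {
    read_pool(c("AACUGAGGAUU", "GGGGGGGGGGG"), c(pos, neg), label = label)
  }
  # no association
  r0 <- fisher_enrichment(mk_pool(10L, 90L, "t"), mk_pool(10L, 90L, "c"),
                          "CUGAGGA", max_mismatches = 0L)
  expect_equal(r0$odds_ratio, 1)
  expect_equal(r0$p_value, 1)
  # the worked 2x2 example [[8,2],[1,9]]
  r1 <- fisher_enrichment(mk_pool(8L, 2L, "t"), mk_pool(1L, 9L, "c"),
                          "CUGAGGA", max_mismatches = 0L)
  expect_equal(r1$p_value, 0.005477, tolerance = 1e-4)
  expect_equal(r1$p_value, oracle_fisher_two_sided(8, 2, 1, 9),
               tolerance = 1e-12)
  expect_equal(r1$odds_ratio, (8 * 9) / (2 * 1))
  # swapping pools inverts the odds ratio, p unchanged
  r1_sw <- fisher_enrichment(mk_pool(1L, 9L, "t"), mk_pool(8L, 2L, "c"),
                             "CUGAGGA", max_mismatches = 0L)
  expect_equal(r1_sw$odds_ratio, 1 / r1$odds_ratio, tolerance = 1e-12)
  expect_equal(r1_sw$p_value, r1$p_value, tolerance = 1e-12)
  # exhaustive check against the oracle for all tables with margins <= 30
  for (rep in 1:200) {
    set.seed(rep)
    a <- sample(0:15, 1L); b <- sample(0:15, 1L)
    cc <- sample(0:15, 1L); d <- sample(0:15, 1L)
    if ((a + b) == 0L || (cc + d) == 0L) next
    got <- fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))$p.value
    expect_equal(got, oracle_fisher_two_sided(a, b, cc, d),
                 tolerance = 1e-9)
  }
  # zero-cell tables get the 0.5 continuity correction, flagged
  rz <- fisher_enrichment(mk_pool(5L, 5L, "t"),
                          read_pool("GGGGGGGGGGG", 10L, label = "c"),
                          "CUGAGGA", max_mismatches = 0L)
  expect_true(rz$continuity_corrected)
  expect_true(is.finite(rz$odds_ratio))
})

test_that("unique-sequence counting unit is available and differs", {
  t_pool <- read_pool(c("AACUGAGGAUU", "CCCUGAGGAUU", "GGGGGGGGGGG"),
                      c(10L, 1L, 1L), label = "t")
  c_pool <- read_pool(c("AACUGAGGAUU", "GGGGGGGGGGG"), c(1L, 10L),
                      label = "c")
  r_reads <- fisher_enrichment(t_pool, c_pool, "CUGAGGA", 0L)
  r_uniq <- fisher_enrichment(t_pool, c_pool, "CUGAGGA", 0L,
                              unit = "unique")
  expect_equal(unname(r_reads$table[1L, ]), c(11, 1))
  expect_equal(unname(r_uniq$table[1L, ]), c(2, 1))
})

test_that("dominant k-mer summarization finds the planted motif", {
  set.seed(15)
  bg <- random_dna(40L, 30L)
  withmotif <- paste0(substr(random_dna(60L, 30L), 1L, 11L), "CTGAGGA",
                      substr(random_dna(60L, 30L), 19L, 30L))
  pool <- dedupe_reads(c(bg, withmotif))
  dk <- dominant_kmer(pool, 7L, top_n = 100L)
  expect_equal(dk$kmer, "CTGAGGA")
  expect_gte(dk$containing_fraction, 0.60)

  expect_equal(dominant_kmer(read_pool("AAAA"), 2L),
               list(kmer = "AA", containing_fraction = 1))
  # tie: every 1-mer of "AC" occurs in the one read; lexicographic wins
  expect_equal(dominant_kmer(read_pool("AC"), 1L)$kmer, "A")
  expect_error(dominant_kmer(read_pool("AC"), 5L), "longer")
})

test_that("per-position variant counts split exact and single-mismatch reads", {
  pool <- read_pool(c("AACUGAGGAUU",   # exact
                      "AACUGAGGCUU",   # single mismatch at motif position 7
                      "GGGGGGGGGGG"),
                    c(2L, 3L, 5L))
  pv <- position_variant_counts(pool, "CUGAGGA")
  expect_equal(pv$reads[pv$category == "exact"], 2)
  # read 2: AACUGAGGC -> window CUGAGGC has mismatch at pattern position 7
  expect_equal(pv$reads[pv$category == "pos7"], 3)
  expect_equal(sum(pv$reads), 5)
  expect_equal(pv$mpm, 1e6 * pv$reads / 10)
})

test_that("enrichment p-value strengthens with the selection factor", {
  p_for_factor <- function(f) {
    pools <- simulate_pools(selex_sim_config(pool_size = 20000,
                                             naive_fraction = 0.01,
                                             enrichment = f, cycles = 2L,
                                             seed = 81L))
    fisher_enrichment(pools$selected, pools$control, "CUGAGGA",
                      max_mismatches = 1L)$p_value
  }
  p <- vapply(c(1.5, 3, 5), p_for_factor, numeric(1L))
  expect_true(all(diff(p) < 0))
  # no selection: selected vs control shows no significant enrichment
  pools0 <- simulate_pools(selex_sim_config(pool_size = 20000,
                                            enrichment = 1, seed = 82L))
  p0 <- fisher_enrichment(pools0$selected, pools0$control, "CUGAGGA",
                          max_mismatches = 1L)$p_value
  expect_gt(p0, 0.01)
})
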