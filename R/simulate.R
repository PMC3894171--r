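# Seeded synthetic-data generators for the three data modalities the
# pipeline consumes: TSS-anchored promoter windows with embedded degenerate
# motifs, selection read pools with controlled motif enrichment, and noisy
# Hill-shaped titration curves. Every generator is a pure function of its
# config (seed included): reruns are byte-identical.

#' Configuration for synthetic promoter windows
#'
#' Defaults encode the study conditions the promoter analysis assumes:
#' 500 genes per pausing group, motif embedding probability 0.6 in paused vs
#' 0.1 in non-paused genes, embedding offsets ~ Normal(+25, 3) truncated to
#' the window (the promoter-proximal pause band), a per-position motif
#' mutation rate of 0.15 (a degenerate genomic element), and an asymmetric
#' A/T-rich sense-strand background composition.
#'
#' @param n_per_group named integer vector, genes per group.
#' @param embed_prob named numeric vector, per-group probability that a
#'   window carries one motif copy.
#' @param background base probabilities (A, C, G, T).
#' @param motif consensus motif to embed.
#' @param mutation_rate per-position probability that an embedded motif base
#'   is replaced by a random different base.
#' @param offset_mean,offset_sd embedding-offset distribution (TSS-relative,
#'   offset of the motif's 5' base), truncated to the window.
#' @param window length-2 inclusive TSS-relative span of each window.
#' @param seed integer seed.
#' @return list of class `promoter_sim_config`.
#' @export
promoter_sim_config <- function(n_per_group = c(paused = 500L,
                                                non_paused = 500L),
                                embed_prob = c(paused = 0.6,
                                               non_paused = 0.1),
                                background = c(A = 0.29, C = 0.205,
                                               G = 0.235, T = 0.27),
                                motif = "CUGAGGA",
                                mutation_rate = 0.15,
                                offset_mean = 25, offset_sd = 3,
                                window = c(-50L, 150L),
                                seed = 1L) {
  stopifnot(all(embed_prob >= 0 & embed_prob <= 1),
            mutation_rate >= 0, mutation_rate <= 1,
            offset_sd >= 0, length(window) == 2L, window[1L] < window[2L],
            identical(sort(names(n_per_group)), sort(names(embed_prob))))
  background <- .check_background(background)
  k <- nchar(motif)
  if (offset_mean < window[1L] || offset_mean > window[2L] - k + 1L) {
    stop("offset_mean must lie within the window span")
  }
  structure(list(n_per_group = n_per_group, embed_prob = embed_prob,
                 background = background, motif = motif,
                 mutation_rate = mutation_rate, offset_mean = offset_mean,
                 offset_sd = offset_sd, window = as.integer(window),
                 seed = as.integer(seed)),
            class = "promoter_sim_config")
}

#' Simulate promoter windows with embedded degenerate motifs
#'
#' Background bases are drawn i.i.d. from the configured composition. With
#' the group-specific probability, one motif copy -- each position
#' independently mutated at the configured rate -- overwrites the window at
#' an offset drawn from the truncated normal offset distribution. At most
#' one copy per window is embedded.
#'
#' @param config a [promoter_sim_config()].
#' @return list with `windows` (data.frame `gene_id`, `sequence`, `group`),
#'   `truth` (one row per gene: `gene_id`, `group`, `embedded`, `offset`,
#'   `instance` -- the possibly mutated motif copy) and `config`.
#' @export
simulate_promoters <- function(config) {
  stopifnot(inherits(config, "promoter_sim_config"))
  motif <- canonicalize_seq(config$motif, allow_ambiguous = FALSE)
  k <- nchar(motif)
  motif_int <- seq_to_int(motif)
  win_len <- config$window[2L] - config$window[1L] + 1L
  min_off <- config$window[1L]
  max_off <- config$window[2L] - k + 1L

  withr::with_seed(config$seed, {
    rows <- list()
    gi <- 0L
    for (grp in names(config$n_per_group)) {
      n <- config$n_per_group[[grp]]
      for (i in seq_len(n)) {
        gi <- gi + 1L
        base_idx <- sample.int(4L, win_len, replace = TRUE,
                               prob = config$background)
        embedded <- runif(1L) < config$embed_prob[[grp]]
        off <- NA_integer_
        inst <- NA_character_
        if (embedded) {
          repeat {
            off <- as.integer(round(rnorm(1L, config$offset_mean,
                                          config$offset_sd)))
            if (off >= min_off && off <= max_off) break
          }
          inst_int <- motif_int
          mut <- runif(k) < config$mutation_rate
          if (any(mut)) {
            for (j in which(mut)) {
              inst_int[j] <- sample(setdiff(1:4, motif_int[j]), 1L)
            }
          }
          pos <- off - config$window[1L] + 1L
          base_idx[pos:(pos + k - 1L)] <- inst_int
          inst <- int_to_seq(inst_int)
        }
        rows[[gi]] <- list(gene_id = sprintf("gene_%s_%04d", grp, i),
                           group = grp, sequence = int_to_seq(base_idx),
                           embedded = embedded, offset = off,
                           instance = inst)
      }
    }
    windows <- data.frame(
      gene_id = vapply(rows, `[[`, character(1L), "gene_id"),
      sequence = vapply(rows, `[[`, character(1L), "sequence"),
      group = vapply(rows, `[[`, character(1L), "group"))
    truth <- data.frame(
      gene_id = windows$gene_id, group = windows$group,
      embedded = vapply(rows, `[[`, logical(1L), "embedded"),
      offset = vapply(rows, `[[`, integer(1L), "offset"),
      instance = vapply(rows, `[[`, character(1L), "instance"))
    list(windows = windows, truth = truth, config = config)
  })
}

#' Configuration for synthetic selection pools
#'
#' Defaults model a nascent-RNA selection experiment: 1e5 reads of 50 nt,
#' 1% of naive reads carrying one exact motif copy, and motif-bearing reads
#' reweighted by `enrichment^cycles` (factor 5, 2 cycles) in the selected
#' pool; the control pool is the naive pool resampled without reweighting.
#'
#' @param pool_size reads per pool.
#' @param read_length read length in nt.
#' @param naive_fraction motif-bearing fraction in the naive pool.
#' @param enrichment per-cycle enrichment factor (>= 1) for motif-bearing
#'   reads.
#' @param cycles number of selection cycles.
#' @param background base probabilities of the random library (uniform by
#'   default, matching a randomized in vitro library).
#' @param motif motif planted in motif-bearing reads.
#' @param seed integer seed.
#' @return list of class `selex_sim_config`.
#' @export
selex_sim_config <- function(pool_size = 1e5, read_length = 50L,
                             naive_fraction = 0.01, enrichment = 5,
                             cycles = 2L,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                             motif = "CUGAGGA", seed = 1L) {
  stopifnot(pool_size >= 1, read_length >= nchar(motif),
            naive_fraction >= 0, naive_fraction <= 1, enrichment >= 1,
            cycles >= 1L)
  background <- .check_background(background)
  structure(list(pool_size = as.integer(pool_size),
                 read_length = as.integer(read_length),
                 naive_fraction = naive_fraction, enrichment = enrichment,
                 cycles = as.integer(cycles), background = background,
                 motif = motif, seed = as.integer(seed)),
            class = "selex_sim_config")
}

#' Simulate naive, selected and control read pools
#'
#' @param config a [selex_sim_config()].
#' @return list with `naive`, `selected`, `control` (each a [read_pool()]),
#'   `truth` (list: `naive_bearing_fraction`, `selected_bearing_fraction`,
#'   per-read bearing flags) and `config`.
#' @export
simulate_pools <- function(config) {
  stopifnot(inherits(config, "selex_sim_config"))
  motif <- canonicalize_seq(config$motif, allow_ambiguous = FALSE)
  k <- nchar(motif)
  withr::with_seed(config$seed, {
    n <- config$pool_size
    L <- config$read_length
    mat <- matrix(sample(NBE_BASES, n * L, replace = TRUE,
                         prob = config$background), nrow = n)
    bearing <- runif(n) < config$naive_fraction
    if (any(bearing)) {
      starts <- sample.int(L - k + 1L, sum(bearing), replace = TRUE)
      motif_chars <- strsplit(motif, "")[[1L]]
      idx <- which(bearing)
      for (j in seq_along(idx)) {
        mat[idx[j], starts[j]:(starts[j] + k - 1L)] <- motif_chars
      }
    }
    reads <- apply(mat, 1L, paste, collapse = "")
    w <- ifelse(bearing, config$enrichment^config$cycles, 1)
    sel_idx <- sample.int(n, n, replace = TRUE, prob = w)
    ctl_idx <- sample.int(n, n, replace = TRUE)
    list(naive = dedupe_reads(reads, label = "naive"),
         selected = dedupe_reads(reads[sel_idx], label = "selected"),
         control = dedupe_reads(reads[ctl_idx], label = "control"),
         truth = list(naive_bearing_fraction = mean(bearing),
                      selected_bearing_fraction = mean(bearing[sel_idx]),
                      control_bearing_fraction = mean(bearing[ctl_idx])),
         config = config)
  })
}

#' Configuration for synthetic binding titrations
#'
#' Defaults mirror the quantitative binding experiments: a 12-point two-fold
#' protein dilution series from 2 uM down (~1 nM), true Kd 44 nM, Hill
#' coefficient 1, and Gaussian response noise of s.d. 0.05 fraction-bound
#' units (F-EMSA) or mP (FP). FP curves use baseline 80 mP and amplitude
#' 120 mP.
#'
#' @param kd_nM true dissociation constant.
#' @param hill_n true Hill coefficient.
#' @param assay `"femsa"` or `"fp"`.
#' @param noise_sd Gaussian noise s.d. on the response scale.
#' @param concentration_nM titration concentrations (ascending).
#' @param replicates number of replicate series.
#' @param seed integer seed.
#' @return list of class `binding_sim_config`.
#' @export
binding_sim_config <- function(kd_nM = 44, hill_n = 1,
                               assay = c("femsa", "fp"),
                               noise_sd = 0.05,
                               concentration_nM = 2000 / 2^(11:0),
                               replicates = 1L, seed = 1L) {
  assay <- match.arg(assay)
  stopifnot(kd_nM > 0, hill_n > 0, noise_sd >= 0, replicates >= 1L,
            length(concentration_nM) >= 5L,
            all(diff(concentration_nM) > 0))
  structure(list(kd_nM = kd_nM, hill_n = hill_n, assay = assay,
                 noise_sd = noise_sd,
                 concentration_nM = concentration_nM,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "binding_sim_config")
}

#' Simulate noisy Hill-shaped titration series
#'
#' response = B + A [P]^n / (Kd^n + [P]^n) + Gaussian noise; F-EMSA uses
#' B = 0, A = 1 with responses clipped to [0, 1], FP uses B = 80 mP,
#' A = 120 mP (unclipped).
#'
#' @param config a [binding_sim_config()].
#' @return list with `series` (list of [titration_series()], one per
#'   replicate), `truth` (the config parameters) and `config`.
#' @export
simulate_titration <- function(config) {
  stopifnot(inherits(config, "binding_sim_config"))
  conc <- config$concentration_nM
  B <- if (config$assay == "femsa") 0 else 80
  A <- if (config$assay == "femsa") 1 else 120
  mu <- B + A * conc^config$hill_n /
    (config$kd_nM^config$hill_n + conc^config$hill_n)
  withr::with_seed(config$seed, {
    series <- lapply(seq_len(config$replicates), function(r) {
      y <- mu + rnorm(length(conc), 0, config$noise_sd)
      if (config$assay == "femsa") y <- pmin(pmax(y, 0), 1)
      titration_series(conc, y, assay = config$assay)
    })
    list(series = series,
         truth = list(kd_nM = config$kd_nM, hill_n = config$hill_n,
                      baseline = B, amplitude = A),
         config = config)
  })
}
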