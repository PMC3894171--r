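#!/usr/bin/env Rscript
# Scan the simulated promoter windows for the NELF-E binding element:
# build the consensus PWM, draw the permutation null, convert scores to
# -log10 empirical p similarity indices, and compare paused vs non-paused
# genes. Run analysis/01_simulate_data.R first.

suppressMessages({
  library(optparse)
  library(nbescan)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20260920L),
  make_option("--sim", type = "character", default = "results/sim"),
  make_option("--null-n", type = "integer", default = 100000L,
              dest = "null_n"),
  make_option("--out", type = "character", default = "results/scan"))))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
p <- function(...) file.path(opts$out, ...)

fa <- read_fasta(file.path(opts$sim, "promoters.fa"))
windows <- data.frame(gene_id = fa$id, sequence = fa$sequence)
groups <- read.delim(file.path(opts$sim, "groups.tsv"))
cat(sprintf("scanning %d windows, null of %s permuted 7-mer scores\n",
            nrow(windows), format(opts$null_n, big.mark = ",")))

# background matches the scanned sequence composition, as it should
bg_counts <- table(factor(unlist(strsplit(windows$sequence, "")),
                          levels = c("A", "C", "G", "T")))
background <- as.numeric(bg_counts) / sum(bg_counts)
names(background) <- names(bg_counts)
pwm <- build_pwm("CUGAGGA", match_probability = 0.85,
                 background = background)
write_pwm_tsv(pwm, p("pwm.tsv"))

null <- build_null(windows, pwm, n = opts$null_n, seed = opts$seed)
tracks <- scan_windows(windows, pwm, null)
write_tracks_tsv(tracks, p("tracks.tsv"))

prof <- average_profile(tracks)
write_tsv_result(prof, p("profile.tsv"))
cat(sprintf("average similarity profile peaks at offset %+d (index %.3f)\n",
            prof$offset[which.max(prof$mean_index)], max(prof$mean_index)))

mat <- heatmap_matrix(tracks, order = "by_max_index")
write.table(data.frame(gene_id = rownames(mat),
                       round(mat, 4), check.names = FALSE),
            p("heatmap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

bm <- best_match_per_gene(tracks, windows, region = c(0L, 50L))
logo <- logo_from_kmers(bm)
write_logo_tsv(logo, p("best_match_logo.tsv"))
cat(sprintf("best-match logo over %d genes; information content %.2f-%.2f bits\n",
            logo$n, min(logo$ic_bits), max(logo$ic_bits)))

cmp <- compare_groups(tracks, groups, region = c(10L, 30L))
print(cmp)
jsonlite::write_json(
  list(region = cmp$region, n = as.list(cmp$n),
       ks_statistic = cmp$ks_statistic, ks_p = cmp$ks_p,
       welch_t_p = cmp$welch_t_p),
  p("group_stats.json"), auto_unbox = TRUE, digits = NA)

pb <- positional_boxplot_stats(tracks)
write_tsv_result(pb$adjacent_tests, p("positional_tests.tsv"))

write_run_manifest(p("manifest.json"),
                   config = list(seed = opts$seed, null_n = opts$null_n,
                                 consensus = "CUGAGGA",
                                 match_probability = 0.85,
                                 background = as.list(background),
                                 region = c(10L, 30L)),
                   inputs = file.path(opts$sim,
                                      c("promoters.fa", "groups.tsv")))
cat("done; outputs under", opts$out, "\n")
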