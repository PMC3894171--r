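#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume:
#   - TSS-anchored promoter windows for paused / non-paused gene groups
#     (FASTA + group TSV + truth manifest),
#   - naive / selected / control selection read pools (pool TSVs),
#   - replicate F-EMSA and FP titration series (TSVs).
# All generators are pure functions of config + seed; the run manifests
# record everything needed to reproduce the files byte-for-byte.

suppressMessages({
  library(optparse)
  library(nbescan)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20260920L),
  make_option("--out", type = "character", default = "results/sim"))))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
p <- function(...) file.path(opts$out, ...)

## promoter windows ---------------------------------------------------------
pcfg <- promoter_sim_config(seed = opts$seed)
prom <- simulate_promoters(pcfg)
write_fasta(prom$windows, p("promoters.fa"))
write_tsv_result(prom$windows[, c("gene_id", "group")], p("groups.tsv"))
write_tsv_result(prom$truth, p("promoter_truth.tsv"))
cat(sprintf("promoters: %d windows (%s), %d with an embedded motif copy\n",
            nrow(prom$windows),
            paste(sprintf("%s n=%d", names(pcfg$n_per_group),
                          pcfg$n_per_group), collapse = ", "),
            sum(prom$truth$embedded)))

## selection pools -----------------------------------------------------------
scfg <- selex_sim_config(seed = opts$seed + 1L)
pools <- simulate_pools(scfg)
for (nm in c("naive", "selected", "control")) {
  write_pool_tsv(pools[[nm]], p(paste0("pool_", nm, ".tsv")))
}
cat(sprintf("pools: %s reads each; motif-bearing fraction %.4f naive -> %.4f selected\n",
            format(scfg$pool_size, big.mark = ","),
            pools$truth$naive_bearing_fraction,
            pools$truth$selected_bearing_fraction))

## titrations ----------------------------------------------------------------
tcfg <- binding_sim_config(kd_nM = 44, hill_n = 1, assay = "femsa",
                           noise_sd = 0.05, replicates = 3L,
                           seed = opts$seed + 2L)
tit <- simulate_titration(tcfg)
for (r in seq_along(tit$series)) {
  s <- tit$series[[r]]
  write_tsv_result(data.frame(concentration_nM = s$concentration_nM,
                              response = s$response),
                   p(sprintf("titration_femsa_rep%d.tsv", r)))
}
cat(sprintf("titrations: %d F-EMSA replicates at true Kd = %g nM\n",
            tcfg$replicates, tcfg$kd_nM))

write_run_manifest(p("manifest.json"),
                   config = list(seed = opts$seed,
                                 promoter = unclass(pcfg),
                                 selex = unclass(scfg),
                                 binding = unclass(tcfg)))
cat("done; outputs under", opts$out, "\n")
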