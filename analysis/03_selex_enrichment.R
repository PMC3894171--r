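#!/usr/bin/env Rscript
# Motif enrichment in the simulated selection pools: MPM-normalized counts
# of NBE-like reads (1 mismatch allowed), Fisher's exact selected-vs-control
# test, the dominant 7-mer among the top sequences, and the per-position
# single-mismatch breakdown. Run analysis/01_simulate_data.R first.

suppressMessages({
  library(optparse)
  library(nbescan)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 20260920L),
  make_option("--sim", type = "character", default = "results/sim"),
  make_option("--pattern", type = "character", default = "CUGAGGA"),
  make_option("--mismatches", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/selex"))))
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
p <- function(...) file.path(opts$out, ...)

pools <- lapply(c(naive = "naive", selected = "selected",
                  control = "control"),
                function(nm) read_pool_tsv(
                  file.path(opts$sim, paste0("pool_", nm, ".tsv"))))

for (nm in names(pools)) {
  cnt <- count_pool_matches(pools[[nm]], opts$pattern, opts$mismatches)
  cat(sprintf("%-8s %s reads, %s motif-positive (MPM %.0f)\n", nm,
              format(pools[[nm]]$total, big.mark = ","),
              format(cnt$positive_reads, big.mark = ","), cnt$mpm))
}

enr <- fisher_enrichment(pools$selected, pools$control, opts$pattern,
                         max_mismatches = opts$mismatches)
print(enr)
jsonlite::write_json(
  list(pattern = opts$pattern, max_mismatches = opts$mismatches,
       unit = enr$unit, table = as.data.frame(as.table(enr$table)),
       mpm = as.list(enr$mpm), odds_ratio = enr$odds_ratio,
       p_value = enr$p_value),
  p("enrichment.json"), auto_unbox = TRUE, digits = NA)

dk <- dominant_kmer(pools$selected, k = nchar(opts$pattern), top_n = 3000L)
cat(sprintf("dominant 7-mer among top 3,000 selected sequences: %s (in %.1f%%)\n",
            dk$kmer, 100 * dk$containing_fraction))

pv <- position_variant_counts(pools$selected, opts$pattern)
write_tsv_result(pv, p("position_variants_selected.tsv"))
pv_c <- position_variant_counts(pools$control, opts$pattern)
write_tsv_result(pv_c, p("position_variants_control.tsv"))
cat("per-position single-mismatch breakdown written for both pools\n")

write_run_manifest(p("manifest.json"),
                   config = list(seed = opts$seed, pattern = opts$pattern,
                                 max_mismatches = opts$mismatches),
                   inputs = file.path(opts$sim,
                                      paste0("pool_",
                                             c("naive", "selected",
                                               "control"), ".tsv")))
cat("done; outputs under", opts$out, "\n")
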