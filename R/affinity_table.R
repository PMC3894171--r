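#' Reported NELF-E binding affinities for RNA targets
#'
#' Published equilibrium dissociation constants (mean +/- s.d. over n
#' independent replicates) for full-length Drosophila NELF-E (dNELF-E),
#' human NELF-E (hNELF-E) and their reciprocal seven-amino-acid RRM swap
#' mutants, binding SELEX-derived aptamers and HIV-1 TAR RNA variants,
#' measured by F-EMSA and fluorescence polarization. Entries reported only
#' as a bound (">2000 nM") are flagged censored with the bound recorded;
#' "ND" (not determined) entries are NA with `censored = FALSE`.
#'
#' The RNA sequences are included so that motif searches can be run on them
#' directly (TAR carries the loop element CUGGGA; TAR+A has one adenosine
#' inserted to create a perfect CUGAGGA element). TAR-dhNBE is an annealed
#' two-strand stem lacking the loop; only its sense strand is given.
#'
#' @return data.frame with columns `protein`, `rna`, `sequence`, `n`,
#'   `femsa_kd_nM`, `femsa_sd_nM`, `femsa_censored`, `fp_kd_nM`, `fp_sd_nM`,
#'   `fp_censored`. For censored entries the `*_kd_nM` column holds the
#'   lower bound.
#' @export
nelfe_affinity_table <- function() {
  tar <- "GGUCUCUCUGGUUAGACCAGAUCUGAGCCUGGGAGCUCUCUGGCUAACUAGGGAACC"
  tar_a <- "GGUCUCUCUGGUUAGACCAGAUCUGAGCCUGAGGAGCUCUCUGGCUAACUAGGGAACC"
  tar_dhnbe <- "GGUCUCUCUGGUUAGACCAGAUCUGAGC"
  napt1min <- "GGCCCCACUGAGGAUGCCCACGGGCGAUUGGGGCCA"
  rows <- list(
    list("dNELF-E", "NApt1min", napt1min, 3L, 44, 22, FALSE, 21, 7, FALSE),
    list("dNELF-E", "NApt25min",
         "GGUCUCCAACUGAGGAUACCGCUCGAGGAAGCGAGUGGCGAUUUGGAGACCU",
         3L, 53, 9, FALSE, 30, 2, FALSE),
    list("dNELF-E", "NApt1+hairpin",
         "GGCCCCACUGAGGAUGCCCACGGGCGUCCUCAGUGGGGCCA",
         3L, 810, 50, FALSE, 470, 170, FALSE),
    list("dNELF-E", "NApt1(3G:Amut)",
         "GGCCCCACUAAAAAUGCCCACGGGCGAUUGGGGCCA",
         1L, 2000, NA, TRUE, NA, NA, FALSE),
    list("dNELF-E", "NApt1-dstem",
         "GGGGACUGAGGAGCAACACGGGCGAUUGGGGCCA",
         3L, 205, 20, FALSE, 270, 130, FALSE),
    list("dNELF-E", "NApt1NBEmut",
         "GGCCCCAUCAAAGAUGCCCACGGGCGAUUGGGGCCA",
         2L, 880, 170, FALSE, NA, NA, FALSE),
    list("dNELF-E", "HIV-1 TAR", tar, 3L, 350, 35, FALSE, 130, NA, TRUE),
    list("dNELF-E", "HIV-1 TAR+A", tar_a, 3L, 59, 2, FALSE, 82, 1, FALSE),
    list("dNELF-E", "HIV-1 TAR-dhNBE", tar_dhnbe, 3L, 2000, NA, TRUE,
         NA, NA, FALSE),
    list("hNELF-E", "NApt1min", napt1min, 3L, 420, 90, FALSE, 140, 10, FALSE),
    list("hNELF-E", "HIV-1 TAR", tar, 3L, 300, 20, FALSE, 200, 10, FALSE),
    list("hNELF-E", "HIV-1 TAR+A", tar_a, 3L, 250, 20, FALSE, 250, 20, FALSE),
    list("hNELF-E", "HIV-1 TAR-dhNBE", tar_dhnbe, 3L, 2000, NA, TRUE,
         NA, NA, FALSE),
    list("dNELF-E(mut)", "NApt1min", napt1min, 2L, 350, 50, FALSE,
         95, 6, FALSE),
    list("dNELF-E(mut)", "HIV-1 TAR", tar, 2L, 270, 10, FALSE,
         130, 10, FALSE),
    list("dNELF-E(mut)", "HIV-1 TAR+A", tar_a, 2L, 280, 30, FALSE,
         120, 10, FALSE),
    list("hNELF-E(mut)", "HIV-1 TAR", tar, 3L, 258, 17, FALSE,
         153, 7, FALSE),
    list("hNELF-E(mut)", "HIV-1 TAR+A", tar_a, 3L, 233, 40, FALSE,
         170, 5, FALSE))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(protein = r[[1L]], rna = r[[2L]], sequence = r[[3L]],
               n = r[[4L]],
               femsa_kd_nM = r[[5L]], femsa_sd_nM = r[[6L]],
               femsa_censored = r[[7L]],
               fp_kd_nM = r[[8L]], fp_sd_nM = r[[9L]],
               fp_censored = r[[10L]])
  }))
  out
}

#' Fetch one affinity-table entry as an affinity estimate
#'
#' @param protein,rna row labels as printed by [nelfe_affinity_table()].
#' @param assay `"femsa"` or `"fp"`.
#' @return an [affinity_estimate()], censored when the table reports only a
#'   bound.
#' @export
affinity_from_table <- function(protein, rna, assay = c("femsa", "fp")) {
  assay <- match.arg(assay)
  tab <- nelfe_affinity_table()
  row <- tab[tab$protein == protein & tab$rna == rna, , drop = FALSE]
  if (nrow(row) != 1L) stop("no unique entry for ", protein, " / ", rna)
  kd <- row[[paste0(assay, "_kd_nM")]]
  sdv <- row[[paste0(assay, "_sd_nM")]]
  cens <- row[[paste0(assay, "_censored")]]
  if (is.na(kd)) stop("Kd not determined for ", protein, " / ", rna,
                      " by ", assay)
  if (cens) {
    affinity_estimate(NA, NA, n = row$n, assay = assay, censored = TRUE,
                      bound_nM = kd, protein = protein, rna = rna)
  } else {
    affinity_estimate(kd, ifelse(is.na(sdv), 0, sdv), n = row$n,
                      assay = assay, protein = protein, rna = rna)
  }
}
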