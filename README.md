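# nbescan

Quantitative analyses of NELF-E RNA binding specificity. NELF-E is the
RNA-recognition-motif subunit of the Negative Elongation Factor complex,
a central player in promoter-proximal pausing of RNA polymerase II; its
consensus RNA target is the NELF-E binding element (NBE, `CUGAGGA`).
This package implements, as tested reusable functions plus a set of
analysis drivers, the three computations that connect the consensus to
its biology:

1. **Promoter scanning** — score every sense-strand 7-mer in
   TSS-anchored windows (−50..+150) with a consensus-derived
   log-likelihood position weight matrix,
   `S(i, β) = log2 p(β|i)/b(β)`, convert scores to empirical p-values
   against a permutation null of shuffled-window 7-mer scores, and map
   the similarity index `−log10 p`. Paused vs non-paused gene groups
   are compared on each gene's maximum index in the +10..+30 pause
   band (two-sample Kolmogorov–Smirnov and Welch t tests).
2. **Selection-pool enrichment** — count reads containing NBE-like
   elements (Hamming mismatch budget, default 1) in SELEX / nascent-RNA
   read pools, normalize to multiplicity per million mapped reads
   (MPM), and test target-vs-control enrichment with a two-sided
   Fisher exact test.
3. **Binding quantification** — fit F-EMSA and fluorescence-polarization
   titrations to the Hill equation
   `y = B + A·[P]^n/(Kd^n + [P]^n)` (Levenberg–Marquardt), aggregate
   replicate Kds, and convert to binding free energies
   `ΔG° = −RT ln Kd` and specificity differences
   `ΔΔG° = −RT ln(Kd_A/Kd_B)` with delta-method error propagation
   (at 298 K, two-fold affinity ≈ 0.41 kcal/mol).

A seeded synthetic-data module generates promoter windows with embedded
degenerate motifs, selection pools with controlled enrichment, and
noisy titrations — with ground-truth manifests — so the whole pipeline
runs and validates without any external download. The published
affinity table for NELF-E constructs (aptamer and HIV-1 TAR RNAs) ships
with the package (`nelfe_affinity_table()`).

## Worked example

Fit three simulated F-EMSA replicates (true Kd 44 nM) and compute a
published specificity difference:

```r
library(nbescan)

sim <- simulate_titration(binding_sim_config(kd_nM = 44, noise_sd = 0.05,
                                             replicates = 3L, seed = 20260922L))
est <- aggregate_replicates(lapply(sim$series, fit_hill))
est
#> Affinity (femsa): Kd = 43.2516 +/- 4.8654 nM (n = 3)

delta_delta_g(affinity_from_table("dNELF-E(mut)", "NApt1min"),
              affinity_from_table("dNELF-E(mut)", "HIV-1 TAR"))
#> ddG0 [dNELF-E(mut)/NApt1min vs dNELF-E(mut)/HIV-1 TAR] = -0.154 +/- 0.087 kcal/mol (T = 298 K)
```

The fitted affinity recovers the generating Kd within its uncertainty,
and the humanized fly construct shows essentially no aptamer-vs-TAR
specificity (|ΔΔG°| well below the 0.41 kcal/mol two-fold line),
whereas the same comparison for wild-type dNELF-E gives +1.23 kcal/mol
— a strong preference for the aptamer. Inserting the single adenosine
that completes the NBE in the TAR loop (TAR → TAR+A) tightens
dNELF-E binding 5.9-fold (59 vs 350 nM).

The numbered drivers under `analysis/` run the full workflow and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R      # windows, pools, titrations + manifests
Rscript analysis/02_promoter_scan.R      # tracks, profile, heat map, logo, group stats
Rscript analysis/03_selex_enrichment.R   # MPM counts, Fisher test, dominant 7-mer
Rscript analysis/04_binding_affinity.R   # Hill fits, ΔG°/ΔΔG° table
```

On the default simulation the scan profile peaks at offset +25/+26
(the embedded band), the paused/non-paused comparison is significant at
p < 1e-30, and the selected pool shows ~4.6-fold odds enrichment of
NBE-like reads over the control.

## Conventions

* Offsets are TSS-anchored; offset 0 = first transcribed base; a 7-mer
  is assigned the offset of its 5′-most base. BED input is 0-based
  half-open (TSS at `start` on `+`, `end − 1` on `−`); error messages
  about FASTA positions are 1-based.
* U and T are interchangeable on input; internally everything is A/C/G/T.
* Ambiguous bases (N) are unscoreable and never match a pattern.
* Ties break 5′-most (scan maxima) or lexicographic (pool summaries).
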