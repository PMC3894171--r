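---
title: "Mapping and quantifying NELF-E binding elements: methods"
author: "nbescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and quantifying NELF-E binding elements: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbescan)
```

NELF-E is the RNA-binding subunit of the Negative Elongation Factor
complex, which stabilizes promoter-proximally paused RNA polymerase II.
Its consensus RNA target, the NELF-E binding element (NBE, `CUGAGGA`),
was defined by in vitro selection; this package implements the three
quantitative analyses that connect that consensus to biology: scanning
promoter-proximal sequence for NBE-like elements, testing selection read
pools for NBE enrichment, and quantifying binding affinity and
specificity from titration data. This vignette documents the models,
the tunable parameters, the numerical conventions, and what the bundled
synthetic-data generators do and do not emulate.

## The motif model

`build_pwm()` turns the consensus into a position weight matrix by a
deliberately simple likelihood model: at each motif position the
consensus base carries probability $p_m$ (`match_probability`, default
0.85) and the remaining mass is split equally over the other three
bases. Scores are log~2~ likelihood ratios against a background base
distribution $b$:

$$S(i, \beta) = \log_2 \frac{p(\beta \mid i)}{b(\beta)},$$

so a 7-mer score is a sum of per-position bits and the consensus 7-mer
is the unique global maximum. Two parameters matter:

* `match_probability` (unitless, in (0.25, 1), default 0.85). The value
  controls how sharply the matrix distinguishes the consensus from
  degenerate variants. 0.85 gives a peaked but non-degenerate matrix
  (a single mismatch costs about 4 bits against a uniform background).
  Because downstream inference runs through *empirical p-values of
  ranked scores*, results are insensitive to the exact value: any
  $p_m$ in a broad range induces the same score ordering among k-mers
  with the same mismatch structure.
* `background` (probabilities over A/C/G/T). This should match the
  composition of the sequence actually scanned; the promoter-scan
  driver estimates it from the input windows. `build_pwm()` refuses
  combinations where a skewed background would make a non-consensus
  base the per-position score maximum, which would silently break the
  interpretation of the matrix.

Log base 2 is a convention choice (bits, consistent with the logo
information content); empirical p-values are invariant to the base.
`logo_from_kmers()` reports per-position base frequencies and
information content $2 - H$ bits with *no* small-sample correction, so
the summary is a deterministic function of its input; for the
thousands of k-mers fed to it here the correction would be negligible
anyway.

RNA and DNA alphabets are canonicalized to one internal alphabet
(U becomes T) so SELEX RNA motifs, nascent-RNA reads and genomic
promoter sequence are directly comparable.

## Promoter scanning and the permutation null

Promoter windows are TSS-anchored on the sense strand — NELF-E binds
nascent RNA, which mirrors the sense strand, so reverse-complement hits
are deliberately ignored — with offset 0 at the first transcribed base
and a default span of −50..+150 (201 bases). A 7-mer is assigned the
offset of its 5′-most base. Windows containing ambiguous bases are
scanned; the affected 7-mers are marked unscoreable and excluded from
maxima and averages rather than imputed.

Scores become p-values by comparison with a permutation null
(`build_null()`): by default (`scheme = "permute_window"`) a window is
sampled uniformly, its letters are permuted uniformly at random, and a
7-mer is read at a uniform offset — equivalently, seven letters are
drawn without replacement from the window. This preserves each
window's base composition exactly, so the null asks "how similar to
the consensus would this sequence look if its letters were shuffled?"
An alternative scheme that shuffles each observed 7-mer in place is
available behind the `scheme` flag; we default to whole-window
permutation because it preserves composition at the scale the windows
were selected (per promoter) while also covering the in-place reading.
The default null size is 100,000 draws (the analysis scripts use
this); validation runs use 2,000–10,000 where the extra resolution is
not needed.

The empirical p-value uses the add-one count

$$p = \frac{1 + \#\{\text{null} \ge s\}}{N + 1},$$

which is strictly positive, so the similarity index $-\log_{10} p$ is
always finite. Because PWM scores on 7-mers take finitely many values,
this estimator is *conservative* (super-uniform) under the null — a
property we test. When exact uniformity matters (calibration checks),
`empirical_pvalue(..., ties = "randomized")` applies the standard
randomized construction
$p = (\#\{>\!s\} + U\,(1 + \#\{=\!s\}))/(N+1)$, $U \sim \mathrm{U}(0,1)$,
which is exactly uniform for scores drawn from any discrete null.

Group inference follows the pausing comparison design: each gene's test
value is its *maximum* similarity index within +10..+30 (the
promoter-proximal pause band), and the paused and non-paused vectors
are compared with a two-sided two-sample Kolmogorov–Smirnov test and a
Welch unequal-variance t-test. Ties in the per-gene best-match search
resolve to the 5′-most offset; this matters only for the logo input,
never for the test values.

## Selection-pool enrichment

Read pools are exact-identity collapsed (`dedupe_reads()`) into unique
sequences with multiplicities; the clustering used upstream of the
original selection analysis is out of scope, and exact identity is the
transparent stand-in. Motif counting permits a mismatch budget
(default 1, i.e. "NBE-like"); a read counts once however many of its
windows match, weights by multiplicity, and normalizes to MPM
(multiplicity per million mapped reads). Matching is full-overlap
Hamming: ambiguous bases never match, and a pattern may not hang off
the read end.

`fisher_enrichment()` builds the 2×2 motif-positive/negative ×
target/control table on read counts (a `unit = "unique"` flag switches
to unique sequences — the original unit is not documented, so both are
exposed) and tests association with a two-sided Fisher exact test.
The reported odds ratio is the sample odds ratio $ad/bc$, with a 0.5
continuity correction applied (and flagged) only when a zero cell
exists. `dominant_kmer()` summarizes a converged pool by the k-mer
present in the most of the top-n sequences; ties are lexicographic
throughout the module, a convention that makes reruns reproducible.

## Binding quantification

Titrations are fit to the Hill equation

$$y = B + A \frac{[P]^n}{K_d^n + [P]^n}$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). For F-EMSA
fraction-bound data the baseline is fixed at $B = 0$ and the amplitude
at $A = 1$; fluorescence polarization is fit on the raw mP scale with
both free. The Hill coefficient is free by default (`fix_n = 1` is
available); $K_d$ is bounded to the positive axis and started at the
concentration nearest half-saturation. A fitted $K_d$ beyond the
titrated range triggers a censoring hint (">2000" style), matching the
convention that such affinities are reported as bounds, not means.
Replicates aggregate as unweighted mean ± sample s.d.; a single
replicate inherits the fit's own standard error.

Free energies use $\Delta G^\circ = -RT \ln K_d[\mathrm{M}]$ with
$R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹ and first-order (delta-method)
error $RT\,\sigma_{K_d}/K_d$; differences
$\Delta\Delta G^\circ = -RT\ln(K_{d,A}/K_{d,B})$ combine uncertainties
in quadrature and are computed as a difference of logs so antisymmetry
is exact in floating point. The default temperature is 298 K: the
assays were run at ambient temperature and 298 K reproduces the
printed specificity value for the humanized construct from the
published dissociation constants (−RT ln(350/270) = −0.154, reported
as −0.15), so it is adopted and exposed as a parameter. At 298 K a
two-fold affinity change is $RT\ln 2 \approx 0.41$ kcal/mol, which is
why 0.5 kcal/mol is a sensible "more than two-fold" guide line.

```{r ddg}
dd <- delta_delta_g(affinity_from_table("dNELF-E(mut)", "NApt1min"),
                    affinity_from_table("dNELF-E(mut)", "HIV-1 TAR"))
dd
```

One known irreproducibility: the published specificity value for the
human protein (−0.25 kcal/mol) cannot be recovered from any pairing of
the *rounded* published dissociation constants (F-EMSA gives −0.20, FP
+0.21); unrounded values were presumably used. The package computes
from the table as printed.

## What the synthetic generators emulate

`simulate_promoters()` draws window bases i.i.d. from a configurable
composition and, with group-specific probability, overwrites one motif
copy (each position independently mutated at rate 0.15 by default — a
degenerate genomic element averaging about one mismatch per copy) at
an offset drawn from a normal distribution centred at +25 with s.d. 3,
truncated to the window. The defaults are the study conditions the
scan is validated against: 500 genes per pausing group with embedding
probabilities 0.6 (paused) vs 0.1 (non-paused), and the +25 ± 3 band
mirrors motif enrichment just upstream of the major pause site. The
default background (A 0.290, C 0.205, G 0.235, T 0.270) is an A/T-rich,
mildly purine-skewed sense-strand composition typical of
promoter-proximal windows; because all four probabilities differ, PWM
scores take several hundred distinct values, which keeps empirical
p-values fine-grained. Deliberate simplifications: order-0 (i.i.d.)
background with no core-promoter elements (TATA/Inr/DPE), at most one
motif copy per window, and no gene-length or annotation structure.
Passing tests therefore demonstrate correct inference under a clean
compositional null, not robustness to real promoter heterogeneity.

`simulate_pools()` models one RAPID-style selection: a random library
(uniform composition, read length 50) in which a fraction (default 1%)
of reads carries one exact motif copy; selection reweights motif-bearing
reads by `enrichment^cycles` (default 5², two amplification-free
cycles) and resamples, while the control pool resamples without
reweighting. No PCR bias or sequencing-error model is included.

`simulate_titration()` adds Gaussian noise (default s.d. 0.05) to an
exact Hill curve over the assay's 12-point two-fold dilution series
from 2 µM down (~1 nM), clipping F-EMSA responses to [0, 1].

Every generator is a pure function of its config and seed: reruns are
byte-identical, and each generator returns a truth manifest so
recovery tests compare against the generating parameters rather than
against re-derived quantities.

## Validation design and problem sizes

The test suite pins the score arithmetic to closed forms, checks the
mismatch scanner, the Fisher p-value and the empirical p-value against
independent brute-force oracles (naive Hamming scan; hypergeometric
enumeration over all tables with row margins ≤ 30; linear-scan
counting), and runs recovery checks at these sizes: calibration with
5,000 background windows against a 10,000-draw null; group separation
at 500 genes per group with a 10,000-draw null; test size under a null
embedding gap over 200 seeded runs at 40 genes per group with
2,000-draw nulls; and Hill-fit recovery over a 4 × 2 × 2 grid of
($K_d$, $n$, noise) with 12 replicates per cell. These sizes give
stable pass/fail behaviour across seeds while keeping a full run in a
couple of minutes; the analysis drivers default to the full
100,000-draw null.

## Limitations

* The scan consumes pre-extracted windows; genome-scale results
  additionally depend on TSS annotation quality, which is out of scope.
* The permutation null conditions on base composition only;
  dinucleotide structure (e.g. CpG avoidance) is not preserved, so on
  real genomes the p-values are calibrated against a composition null,
  not a full sequence-structure null.
* The mismatch scanner handles fixed-length patterns with a Hamming
  budget; it is not a general pattern language, and elements related
  to the consensus by insertion/deletion (as the wild-type TAR loop is)
  are invisible to it by design.
* Censored affinities propagate as bounds and are excluded from
  free-energy differences rather than imputed.
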