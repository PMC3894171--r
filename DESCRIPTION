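Package: nbescan
Title: NELF-E Binding Element Scanning, Enrichment Statistics and Binding
    Affinity Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analyses of NELF-E RNA binding specificity around
    the consensus NELF-E binding element (NBE, CUGAGGA). Builds log-likelihood
    position weight matrices from a consensus motif and scans TSS-anchored
    promoter windows, converting scores to empirical p-values against a
    permutation null to map motif enrichment in promoter-proximal pause
    regions; counts mismatch-tolerant motif occurrences in SELEX and nascent
    RNA (GRO-RNA) read pools with multiplicity-per-million normalization and
    Fisher's exact enrichment tests; fits Hill-equation binding curves to
    F-EMSA and fluorescence polarization titrations and converts dissociation
    constants to binding free-energy differences with propagated uncertainty.
    Includes seeded synthetic-data generators for promoter windows, selection
    pools and titrations so every stage runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    methods,
    minpack.lm,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
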