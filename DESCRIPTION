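Package: tillingr
Title: EMS Mutation Spectra, TILLING Screen Design and Pooled-Screen
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and evaluating TILLING (Targeting Induced
    Local Lesions In Genomes) reverse-genetics screens of EMS-mutagenized
    plant populations. Enumerates the GC-to-AT transition spectrum of the
    standard genetic code and classifies silent, mis-sense and nonsense
    outcomes; profiles coding sequences for stop-codon potential; estimates
    mutation density from screen results with GC-content normalization and
    extrapolates per-plant and population-wide mutation loads; computes
    screen-design probabilities (expected mutation yield, probability of
    recovering a nonsense allele, genome saturation, backcross load decay);
    and forward-simulates an EMS-mutagenized diploid M2 population with
    one-dimensional pooling and edge-attenuated detection so every estimator
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
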