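Package: lowdivscan
Title: Genome Scans for Diversity Peaks, Genetic Load, and Runs of
    Homozygosity in Low-Diversity Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed genome-scan diagnostics for endangered, low-diversity
    diploid genomes: nucleotide-diversity peak detection in non-overlapping
    windows with mappability and depth-of-coverage filtration, Weir-Cockerham
    window F_ST contrasts between a focal and a reference species, 0-fold/4-fold
    degenerate-site genetic-load proxies and coding-effect spectra, hidden
    Markov model calling of runs of homozygosity with F_ROH, per-gene
    CDS-variant-proportion summaries of polymorphic genes, and a Monte Carlo
    test for diversity-peak windows shared between two species. A seeded
    synthetic-genome generator emulates the statistical structure the scan
    assumes so every stage can be exercised end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
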