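Package: zwscan
Title: Sex-Determination Region Discovery, Strata Dating and Selective Sweep
    Scans for ZW Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the sex-determination region (SDR) of a ZW plant genome
    from pooled female/male read-depth ratios integrated with sex-linked SNP
    evidence (allelic association, Weir-Cockerham Fst, female-specific SNP
    blocks), dates W/Z evolutionary strata from inversion-aware gene-pair
    divergence using the Nei-Gojobori method and a molecular clock, and scans
    for domestication selective sweeps by intersecting wild/cultivar
    diversity-ratio outliers with LD-based omega-statistic outliers. Includes
    windowed population-genetic statistics (pi, Watterson's theta, Tajima's D,
    Fst, LD decay, folded SFS) and a seeded synthetic-data generator that
    emulates pooled coverage tracks, sex-linked variant panels, wild/cultivar
    genotype panels with planted sweeps, W-Z anchor gene pairs and genetic
    maps, together with machine-readable truth sets so every detector is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
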