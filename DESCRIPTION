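Package: thermoevolve
Title: Evolve-and-Resequence Analysis of Thermal Adaptation from Pool-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing replicated evolve-and-resequence (E&R)
    experiments with pooled sequencing. Provides Wright-Fisher forward
    simulation with additive selection and Pool-Seq sampling noise,
    PoPoolation2 sync-format input/output, replicated Cochran-Mantel-Haenszel
    selection scans with simulation-based false-positive-rate calibration,
    temporal effective-population-size and selection-coefficient inference,
    reconstruction of selected haplotype blocks from correlated allele
    frequency trajectories, a quantitative-trait simulator under bounded
    Gaussian stabilizing selection for quantifying the contribution of focal
    large-effect loci, and resampling tests for clinal variation, together
    with synthetic-data generators for the complete pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
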