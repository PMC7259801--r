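Package: splicecard
Title: Splice-Isoform Assay Simulation and Cardiac Phenotyping Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tool-chain for studying alternative splicing of
    duplicated jnk1 genes (jnk1a/jnk1b) during zebrafish heart development.
    Implements an in-silico semi-quantitative RT-PCR splicing assay
    (amplicon prediction, IUPAC restriction digest, densitometry-based
    transcript proportion estimation with ef1-alpha and PCR-efficiency
    normalisation), peptide divergence classification between splice
    variants, and cardiac phenotyping metrics (cardiomyocyte track speed,
    velocity and wandering index; chamber-resolved nuclei counts; M-mode
    kymograph reslicing; fractional shortening and heart rate; expression
    field area). A seeded synthetic-data generator emulates every wet-lab
    input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
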