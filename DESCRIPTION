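Package: ernamd
Title: Enhancer RNA Origin Detection and Motif Displacement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for regulatory-genomics analysis of bidirectionally
    transcribed enhancers. Detects enhancer RNA (eRNA) origins from
    strand-specific nascent-transcription coverage by deterministic peak
    pairing, scans genomes for transcription factor binding motifs with a
    position weight matrix scanner whose score threshold is calibrated to an
    exact null p-value by dynamic programming, computes motif displacement
    (MD) scores measuring motif co-localization with eRNA origins together
    with two-proportion z-tests between conditions and barcode distance
    histograms, performs pseudo-bulk per-nucleus contrasts of chromatin
    accessibility (logistic regression) and gene expression (negative
    binomial regression) across disease groups and genotypes, and converts
    tiled MNase-qPCR Ct tables into relative nucleosome-protection profiles.
    A synthetic-data module generates every input with known ground truth so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    graphics,
    grDevices,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
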