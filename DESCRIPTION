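Package: ddrquant
Title: Quantitative Proteomics Pipelines for AP-MS Interactomes and TMT
    PTM Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of affinity-purification mass spectrometry
    (AP-MS) interactome experiments and TMT isobaric-label proteome /
    acetylome / phosphorylome experiments. Reads MaxQuant-style
    proteinGroups and PTM-site tables, applies peptide-evidence and
    contaminant filters, imputes left-censored missing intensities from a
    down-shifted normal distribution, renormalizes AP-MS runs against a
    k-means-derived background protein cluster, corrects TMT reporter
    intensities for isotopic label impurities, performs within-plex median
    and between-plex internal-reference-scaling (IRS) normalization,
    normalizes PTM-site intensities to parent-protein abundance, and tests
    for differential abundance with an empirical-Bayes moderated
    t-statistic under Benjamini-Hochberg FDR control. Downstream tools
    cover regulated-site calling, SQ-motif annotation, cross-study SILAC
    ratio integration, ortholog mapping, confidence-filtered interaction
    networks, and profile clustering. A seeded synthetic-data generator
    with recorded ground truth supports recovery and calibration testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
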