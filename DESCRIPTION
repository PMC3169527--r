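Package: decaycoupling
Title: Coupled mRNA Production and Degradation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of genome-wide coupling between mRNA
    production and degradation in stress-responding yeast. Provides a
    deterministic forward simulator of co-transcriptional Rpb4/7 imprinting
    with a limited, redistributable cytoplasmic decay-machinery pool; a
    microarray-like observation layer with known distortions; the bespoke
    reference-profile and spike-in normalizations needed for
    transcription-arrest decay courses; first-order half-life estimation
    with goodness-of-fit filtering; cubic-spline response profiling;
    stability-change versus abundance-change coupling statistics (including
    fold-enrichment contingency analysis); and Spearman/average-linkage
    clustering of concatenated two-strain response profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
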