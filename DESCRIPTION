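Package: combisom
Title: Integrative Multi-Omics Portrayal with Combined Self-Organizing Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint self-organizing-map (SOM) portrayal of patient-matched gene
    expression, DNA promoter methylation and copy-number matrices. Per-gene
    profiles from the three omics layers are centralized, harmonized to a
    common scale, concatenated with tunable modality weights and trained into
    a single SOM whose metagenes are then decomposed back into mutually
    aligned per-modality "portraits". Downstream tools derive spot modules,
    variance and covariance maps, signed square-root covariance (ScoV) maps,
    sample-wise gene-set Z scores with ternary Gex/Dme/CNV compositions,
    metagene-resolved hazard-ratio maps, and sample-similarity heatmaps and
    networks. A configurable synthetic-cohort generator with ground truth
    supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    igraph,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
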