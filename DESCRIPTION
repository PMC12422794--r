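Package: hallmarkScore
Title: Hallmark-Decomposition Scoring of Aging-Related Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how strongly a disease aligns with the biology of
    aging from its target genes. Disease targets are repeatedly subsampled
    and tested for over-representation in a hallmark-annotated pathway
    library (hypergeometric test); enriched pathways are aggregated into
    per-hallmark partial scores, combined with an entropy-based diversity
    factor into a total aging-alignment score, and reported with resampling
    confidence intervals, Benjamini-Hochberg corrected significance, and
    cross-disease 0-100 normalization. Includes a synthetic-world generator
    with planted hallmark signal for end-to-end validation, readers and
    writers for GMT libraries, hallmark annotation tables and target
    association tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
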