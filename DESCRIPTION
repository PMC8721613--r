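Package: cocultex
Title: Marker-Based Mixture Deconvolution and Additivity Screening for
    Coculture Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses bulk RNA-seq expression of two-population cocultures
    against their matched monocultures. Estimates the fraction of the
    coculture transcriptome contributed by one population from
    population-exclusive marker genes (e.g. Y-chromosome genes in
    sex-mismatched mesenchymal stromal cell / chondrocyte cocultures),
    predicts each gene's coculture expression under an additive mixture
    model, calls genes whose observed expression deviates from additivity
    by fold change, and intersects calls across donor pairs into consensus
    sets. Includes a synthetic-data generator with known ground truth for
    validating every stage, and an optional parametric-bootstrap p-value
    for fold-change deviations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
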