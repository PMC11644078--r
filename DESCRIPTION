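Package: metabatch
Title: Time-Course Metabolomics of Plant Batch Cell Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for GC-MS metabolite profiles sampled along the
    growth cycle of plant suspension batch cultures (lag, proliferation,
    elongation, stationary and death phases). Implements the standard
    metabolomics preprocessing chain (sample-median normalization, log
    transform, autoscaling, k-nearest-neighbour imputation), PCA with group
    confidence ellipses, OPLS-DA with variable-importance (VIP) scores and
    univariate testing, preranked metabolite-set enrichment on OPLS-DA
    loadings, correlation-network mapping of temporal profiles with signed
    force-directed layout and k-means clustering, inside/outside-pathway
    correlation contrasts, and Canberra-distance variability fingerprints of
    time points. Ships a synthetic batch-culture metabolome generator with
    known archetype and pathway ground truth, plus a calibrated
    medium-kinetics model (sucrose hydrolysis, hexose uptake, biomass
    growth, pH), used to validate every stage of the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust
Config/testthat/edition: 3
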