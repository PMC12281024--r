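Package: metabarDiet
Title: Curation of DNA Metabarcoding Diet Data and Diet-Microbiome-Body-Mass
    Association Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for curating replicated DNA-metabarcoding diet data and
    relating diet composition to gut-microbiome structure and host condition.
    Implements an iterative PCR-replicate outlier filter based on
    within-sample versus between-sample dissimilarity distributions,
    relative-read-abundance (RRA) normalisation with abundance and
    best-identity filters, taxonomic aggregation, Hill-number and Chao1
    diversity, common scaling of amplicon libraries, first-principles
    Bray-Curtis, Mantel and sequential PERMANOVA statistics, and a
    direct/indirect path-effect decomposition of diet effects on body mass
    mediated by microbiome diversity. Includes a synthetic-study generator
    with known ground truth (planted outlier replicates, artefact MOTUs,
    known path coefficients) so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Sequencing, Preprocessing,
    QualityControl, StatisticalMethod
RoxygenNote: 7.3.3
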