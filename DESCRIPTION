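Package: microrepeat
Title: Partitioning Biological and Technical Variation in Microbiome Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how reproducibly 16S amplicon sequencing
    measures host-associated microbial communities. Partitions variation in
    alpha diversity, community dissimilarity, and individual taxon abundances
    into among-host (biological) and within-host (technical) components;
    estimates repeatability/reproducibility r = s2A/(s2A + s2W) with bootstrap
    confidence intervals; fits overdispersed Poisson (Poisson-lognormal)
    models for per-taxon repeatability; characterises the relationship between
    taxon abundance and reproducibility with a logistic curve; and provides a
    hypothesis-test battery (mixed-model likelihood ratio tests, PERMANOVA
    variants, Mantel tests, median-based Levene tests, and the Feltz-Miller
    test for equality of coefficients of variation). Includes a synthetic-data
    generator with known variance structure for validation, plus rarefaction,
    prevalence filtering, taxonomy aggregation, and phylogenetic diversity
    metrics (Faith's PD, unweighted and weighted UniFrac).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    minpack.lm,
    permute,
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
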