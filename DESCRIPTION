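Package: reefscape
Title: Comparative Seascape Connectivity Analysis of Genetic and Species
    Beta-Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing genetic and species beta-diversity across
    ocean basins with contrasting seascape configurations. Computes Hedrick's
    standardized genetic differentiation (G''ST) from SNP genotypes with
    quality filtering and iterative loci/individual subsampling, partitions
    Jaccard species dissimilarity into turnover and nestedness components
    (Baselga framework), derives least-cost in-water geographic distances
    over gridded land/sea masks, and fits maximum-likelihood
    population-effects (MLPE) linear mixed models to stacked pairwise
    distance data for isolation-by-distance and species-genetic diversity
    correlation analyses, with Nakagawa-Schielzeth marginal and conditional
    R-squared. A seed-deterministic synthetic two-basin generator produces
    seascapes, genotypes and community tables with tunable distance-decay
    structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    geosphere,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
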