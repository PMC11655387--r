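Package: archoffset
Title: Genomic Offset and Assisted Gene Flow Planning for Island Metapopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landscape-genomics toolkit for conservation planning in island
    systems: VCF genotype filtering, LD pruning and mode imputation;
    Weir-Cockerham F_ST, PCA, identity-by-state distances and
    isolation-by-distance fits; redundancy analysis (RDA) based
    genotype-environment association with variance partitioning and
    outlier-SNP detection; PCNM spatial eigenvectors; gradient-forest
    turnover functions with a compiled regression-forest backend; genomic
    offsets between seed sources and planting sites under status-quo,
    ecosystem-preservation and species-preservation scenarios; a climate
    suitability index and ranked seed-source/planting-site pairings; and a
    synthetic island-archipelago simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    minpack.lm,
    geosphere,
    jsonlite
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
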