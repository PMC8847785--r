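Package: restrans
Title: Resident and Transient Microbiome Members from Common-Garden ASV Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies members of a host-associated microbiome as resident
    (population-restricted) or transient (environmentally exchanged) from an
    ASV count table and sample metadata spanning field and common-garden
    samples. Provides sample-depth and prevalence filtering, binary
    Sorensen-Dice dissimilarities, permutational multivariate analysis of
    variance and homogeneity-of-dispersion tests implemented from first
    principles, Wilcoxon rank-sum contrasts of within- versus
    between-population dissimilarities, divergence-over-time regression, a
    per-ASV flexibility score with Hartigan's dip test for bimodality, and a
    synthetic common-garden data generator with known ground truth for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
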