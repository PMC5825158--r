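Package: clonalclock
Title: Tip-Dated Substitution Rates and Selection Inference in Quasi-Clonal
    Plant Lineages
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for dated whole-genome samples of a selfing,
    effectively non-recombining plant lineage, such as a colonizing
    haplogroup sampled from herbaria and modern populations.  Implements
    substitution-rate estimation by net-distance regression on collection
    dates with bootstrap confidence intervals, annotation-stratified rates,
    generation-time rescaling, founding-date (TMRCA) inference, mutation
    accumulation line rate estimation, classical diversity statistics
    (Watterson's theta, pi, Tajima's D), an unfolded site frequency
    spectrum oriented by first appearance in dated samples, purifying
    selection contingency and Kolmogorov-Smirnov tests, kinship-based chip
    heritability, permutation-null genome-wide association with Grantham
    scoring of amino-acid changes, and a quasi-clonal lineage simulator
    for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    ape,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
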