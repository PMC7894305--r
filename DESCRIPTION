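Package: jointsfs
Title: Two-Population Demographic Inference from the Joint Site Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the divergence history of a pair of diploid
    populations from genotype data: deterministic VCF filtering (depth, quality,
    allele balance, per-population missingness, an exact Hardy-Weinberg test,
    indel proximity and physical thinning), outgroup polarization, construction
    of the unfolded joint site frequency spectrum with hypergeometric
    projection, a moment-based engine for expected spectra under multi-epoch
    isolation/migration/secondary-contact models with a genomic-island
    migration mixture, Poisson composite-likelihood fitting with multi-start
    optimization, nonparametric SNP bootstrap, AIC-based model ranking with
    Akaike weights and evidence ratios, and conversion of fitted parameters to
    individuals and years. Ships a catalog of 107 two-population models and a
    coalescent simulator for generating test data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
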