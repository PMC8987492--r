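Package: boapred
Title: Breed-of-Origin-Aware Multi-Breed Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for numerically small admixed livestock
    breeds that carry introgressed haplotype segments from a large
    mainstream breed. Implements an origin-split SNP-BLUP model in which
    each marker has one additive effect per breed of origin and the
    effects are correlated across origins through a Kronecker-structured
    covariance (the breed-origin-of-alleles, BOA, model), together with
    within-breed and multi-breed SNP-BLUP/GBLUP baselines. Includes a
    two-breed admixture simulator (Balding-Nichols breed divergence, a
    historic migrant pulse, gene dropping with Haldane recombination),
    segment-based assignment of haplotype origins against purebred
    reference panels, correlated QTL-effect trait simulation, and
    sire-family cross-validation with a grid search for the across-origin
    effect correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
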