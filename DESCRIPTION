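Package: lampreyNb
Title: Cohort Identification and Effective Breeding Number Estimation from
    Larval SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genetic assessment of spawning populations of
    semelparous fishes (developed around sea lamprey, Petromyzon marinus)
    from SNP genotypes of stream-collected larvae. Implements locus and
    individual quality control including paralog screening from
    heterozygosity and heterozygote read-ratio deviation, sibship and
    pedigree reconstruction of unsampled parents, Bayesian Gaussian mixture
    inference of larval age classes from body length with two
    model-selection procedures (overfitted-mixture weight truncation and
    birth-death MCMC), pedigree-guided reconciliation of length-based cohort
    assignments, and per-cohort estimators of the effective number of
    breeders (linkage-disequilibrium and sibship-frequency methods), the
    minimum number of spawners, parentage accumulation curves, and
    incidence-based richness extrapolation (Chao2, first-order jackknife).
    Includes a fully seeded simulator of multi-cohort semelparous spawning
    scenarios with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
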