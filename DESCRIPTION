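Package: geoassign
Title: Geographic Assignment of Individuals from Microsatellite Genotypes
    and mtDNA Haplogroups
Version: 0.1.0
Authors@R:
    person("Limbe", "Forensics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the geographic origin of individuals of unknown
    provenance from multilocus microsatellite (STRP) genotypes and
    mitochondrial haplogroup labels, using a Bayesian spatially smoothed
    allele-frequency model over georeferenced reference samples.  Provides
    a smoothed assignment method (SAM) that assigns unknowns to sampled
    reference sites, a continuous assignment method (CAM) that assigns
    unknowns to arbitrary coordinates inside a habitat boundary polygon,
    median-joining haplotype network construction with hypermutable-site
    masking, a full validation suite (leave-one-out cross-validation,
    distance quantiles, zone containment, mtDNA concordance, negative
    controls), and a seeded synthetic-landscape generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
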