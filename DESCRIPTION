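Package: hlassp
Title: Real-Time PCR-SSP Class I HLA Genotyping Toolkit
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a sequence-specific-primer (SSP) real-time PCR
    genotyping platform for the common East African class I HLA-A, -B and
    -C alleles.  Encodes the published reaction panel as machine-readable
    fixtures, derives and audits allele and genotype reactivity patterns
    (union codes), calls per-reaction reactivity from paired Ct values,
    decodes aggregate patterns into genotypes, scores carrier-level
    validation performance, and provides the downstream population-genetics
    toolkit (allele frequencies, coverage, Hardy-Weinberg testing,
    Cavalli-Sforza chord distances, neighbor-joining trees, principal
    coordinates) together with an in-silico SSP reactivity predictor and a
    synthetic-data simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
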