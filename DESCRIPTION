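Package: breedassign
Title: Breed-Informative SNP Panel Selection and Forensic Breed Assignment
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Selection of maximally breed-informative SNP markers from dense
    genotyping panels using the delta (absolute allele-frequency difference)
    statistic, partial-Bayesian (Rannala-Mountain) individual assignment with
    leave-one-out validation, exclusion-simulation testing against breed
    reference populations, and forensic pairwise-contrast power analysis
    yielding posterior probabilities of correct breed assignment.  Includes
    population-genetic summaries (Weir-Cockerham F_ST, Reynolds distance,
    neighbour-joining trees with locus bootstrap, EM-based r-squared linkage
    disequilibrium), PLINK-style PED/MAP and CSV genotype input/output, and a
    Balding-Nichols breed-structured genotype simulator for offline testing
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
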