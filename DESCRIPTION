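Package: pangotrace
Title: Conservation Genetics and Forensic Tracing of the Pangolin Trade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic analysis and forensic trade tracing for
    microsatellite and mitochondrial control-region data from hunted and
    traded wildlife, built around the white-bellied pangolin of the Dahomey
    Gap. Implements diversity statistics (allelic richness by rarefaction,
    unbiased expected heterozygosity, Hardy-Weinberg tests), Weir-Cockerham
    F-statistics with permutation significance, forensic identity statistics
    (genotype matching, probability of identity and its sibling variant,
    minimum-loci curves), generalized rarefaction of private alleles over
    population combinations with cross-validation against observed private
    alleles for assigning market individuals to source forests, mtDNA
    haplotype diversity and neutrality tests (Tajima's D, Fu's Fs,
    Ramos-Onsins and Rozas' R2, Harpending's raggedness) with
    neutral-coalescent null distributions, Kimura two-parameter lineage
    assignment, and Mantel tests of isolation by distance. A seeded
    synthetic-data generator (Balding-Nichols population structure,
    inbreeding, planted private alleles, market sampling, Kingman
    coalescent sequences) lets the whole pipeline run self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
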