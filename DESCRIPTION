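Package: autozygr
Title: Autozygosity Mapping and Variant Prioritization in Consanguineous Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pedigree-aware analysis of runs of homozygosity (ROH) and
    inheritance-model variant prioritization for consanguineous disease
    cohorts. Computes kinship and inbreeding coefficients by the standard
    recursion and the pedigree-expected autozygous burden; detects ROH from
    genotype data with a sliding-window caller; segregates ROH across
    affected and unaffected siblings; applies explicit de novo, recessive
    and X-linked variant filters with read-level thresholds; tests de novo
    burden against a per-gene mutability model (Poisson observed/expected
    and a multinomial permutation null for recurrence); and detects
    multilocus pathogenic variant (MPV) carriers. A gene-drop simulator
    generates multiplex consanguineous families with known autozygous
    segments, planted causal variants and read-level noise, so every step
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
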