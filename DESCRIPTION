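Package: breedscape
Title: Breed Demography from SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterising closed animal populations (dog breeds and
    similar livestock populations) from SNP-array genotypes: PLINK and phased-VCF
    input/output, marker and sample quality control with duplicate and relatedness
    pruning, bootstrapped neighbor-joining phylogenies from identity-by-state
    distances, runs-of-homozygosity and inbreeding metrics with a threshold-based
    breed-status classifier, windowed identity-by-descent haplotype-sharing
    statistics with an empirical cross-clade null, and divergence dating from
    shared-haplotype length. Includes a forward-in-time Wright-Fisher breed-cohort
    simulator that tracks founder mosaics exactly, providing ground-truth identity
    by descent and autozygosity for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
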