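Package: nativeocs
Title: Optimum Contribution Selection with Kinship at Native Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Optimum contribution selection (OCS) for local livestock breeds
    with historical introgression from other breeds. Computes pedigree-based
    classical kinship and origin-aware kinships (the probability that two
    alleles are identical by descent or of migrant origin, and the kinship
    conditional on native descent), migrant contributions of all animals, and
    solves constrained contribution-optimization scenarios that balance
    genetic gain, rate of inbreeding, genetic originality, and diversity of
    native alleles. Includes gene-dropping and exhaustive transmission
    enumeration oracles, a synthetic-pedigree generator with configurable
    migrant waves and breeding-value/migrant-contribution correlation, an
    interior-point solver for the quadratically constrained scenarios, and
    tabular scenario reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
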