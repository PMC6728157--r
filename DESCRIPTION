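Package: beaconr
Title: Federated Genomic Allele Discovery Beacons with Re-Identification
    Risk Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and studying genomic data-discovery
    beacons: services that answer yes/no allele-presence queries over
    VCF-backed variant datasets. Provides exact-match allele indexes
    built from VCF files, the two-function beacon query protocol with
    tiered progressive disclosure and consent-code purpose gating, an
    information-budget meter that refuses service before
    re-identification confidence is reachable, beacon-network
    federation with origin-obscuring aggregate beacons, and a
    membership-inference attack simulator over synthetic diploid
    populations that quantifies re-identification power and evaluates
    the budgeting defense.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
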