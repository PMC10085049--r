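Package: cnvrcons
Title: High-Confidence Copy Number Variation Regions by Multi-Platform Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds high-confidence copy number variation regions (CNVR) by
    consensus across whole-genome-sequencing CNV callers (CNVnator, DELLY) and
    SNP-array calls (PennCNV). Reads caller-native output formats, applies
    per-caller retention filters, merges calls into regions by transitive
    1-bp overlap, and derives two consensus sets: a population-level set
    (cross-platform reciprocal-overlap matching plus a minimum carrier
    frequency) and a per-animal set (within-sample dual-platform agreement).
    Includes comparison against external CNVR catalogues, gene/QTL overlap
    annotation, and a call-level simulator with per-caller noise models so the
    whole pipeline is testable against a known truth landscape.
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
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
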