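Package: refaudit
Title: Auditing DNA Barcode Reference Libraries and Metabarcoding MOTUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit DNA barcode reference libraries and analyse
    metabarcoding molecular operational taxonomic units (MOTUs). Implements
    record filtering with a rejection log (length, species name, cluster
    label, QC flags, tag-coded names, stop-codon pseudogene screen),
    Kimura two-parameter distances with pairwise deletion, neighbour-joining
    trees, single-linkage MOTU clustering across a threshold sweep with a
    barcode-gap partition score, singleton/concordant/discordant cluster
    reports, A-E species grading, regional checklist coverage analysis,
    MOTU-to-species ratio richness extrapolation, majority-rule consensus
    taxonomy with outlier exclusion, and a synthetic-data generator with
    planted truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
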