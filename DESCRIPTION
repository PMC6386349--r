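Package: idnatax
Title: Taxonomic Assignment of Invertebrate-Ingested DNA from Leech Bloodmeals
Version: 0.1.0
Authors@R:
    person("iDNA", "Pipeline Maintainers", email = "idnatax@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying vertebrate hosts from DNA ingested by
    blood-feeding terrestrial leeches (iDNA). Provides a desk-scale local
    homology search (Smith-Waterman with Karlin-Altschul E-values), the
    best-hit identification decision rules used in leech-gut surveys
    (E-value retention and leech-contamination screens, percent-identity
    margins, lowest-common-ancestor rank demotion, anthropogenic-taxon
    exclusion), cross-locus (12S/16S) reconciliation, a reference-database
    coverage-aware consensus that resolves database-gap misidentifications
    in multi-locus shotgun data, survey-level summary statistics, and a
    synthetic-data generator with known ground truth for validating all of
    the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
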