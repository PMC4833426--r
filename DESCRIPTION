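Package: promprof
Title: Compound Promiscuity Profiling from Screening Outcome Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aggregates raw compound-by-assay screening outcome records and
    assay metadata, in the style of large-scale PubChem BioAssay analyses,
    into per-compound promiscuity profiles. Qualifies primary and
    confirmatory assays, filters outcomes to unambiguous active/inactive
    calls, distinguishes assay promiscuity (active assays) from target
    promiscuity (unique annotated targets), partitions compounds by
    assay-category coverage, censuses consistently inactive dark chemical
    matter, summarizes promiscuity degrees with binned five-number
    statistics, and annotates frequent hitters with PAINS substructure
    flags. Includes a seeded synthetic-data generator with ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    ChemmineR
Suggests:
    ChemmineOB,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
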