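Package: tcrshare
Title: Paired-Site TCR-Beta Repertoire Overlap and Clonotype Sharing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the clonal overlap of T-cell receptor beta
    (TCRB) repertoires sampled from paired anatomical sites, such as the left
    and right draining lymph nodes of one individual. Reads AIRR rearrangement
    tables and legacy clonotype-table dialects, applies a productivity and
    copy-number filter followed by a per-sample above-median abundance filter,
    and computes abundance-weighted Morisita-Horn similarity, shared-clonotype
    overlap tables with regression fits, top-N relative intersections,
    cross-individual clonotype sharing spectra, and TRBV/TRBJ gene-segment
    usage comparisons with Sidak family-wise correction. Includes a seeded
    generator of synthetic paired repertoires with heavy-tailed clone sizes,
    a shared dominant clonotype block, public background clonotypes, and
    temporal decay of dominant clones, so every statistic can be exercised and
    validated without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
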