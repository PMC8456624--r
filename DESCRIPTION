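Package: ecscreen
Title: Enzyme-Constrained Metabolic Modeling with Transcriptome-Derived
    Bounds and In Silico Rescue Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for GECKO-style enzyme-constrained flux balance analysis
    and its integration with transcriptome data. Builds enzyme-constrained
    metabolic models with kcat coupling and a total enzyme pool bound,
    solves single-objective and lexicographic linear programs, samples
    feasible flux distributions under randomly weighted paired objectives,
    translates differential-expression fold changes into per-enzyme usage
    bounds, and runs an in silico single-enzyme rescue screen with
    hypergeometric gene-set enrichment of the rescuers. Also provides
    growth-curve metrics (doubling time, lag phase, final OD600), a
    poorly-induced-gene expression classifier with CPM filtering and
    read-fraction accounting, and seeded generators for synthetic models,
    expression tables, count matrices, and growth curves that emulate a
    yeast diauxic-shift study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
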