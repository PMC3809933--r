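Package: chrysodiag
Title: Species-Specific PCR Diagnostics for the Penicillium chrysogenum Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover species-diagnostic alignment sites in multilocus
    sequence data from the four cryptic species of the Penicillium chrysogenum
    complex (P. chrysogenum, P. rubens, P. chainii, P. floreyi), to design
    3'-anchored species-specific PCR primer pairs with amplicons of 100-200 bp,
    to classify isolates by in-silico PCR under a no-overlapping-positives
    specificity contract, and to analyse location-structured isolate counts
    (chi-square independence and goodness-of-fit, one-way ANOVA, Tukey-Kramer,
    proportions, inhaled-conidia exposure). Includes distance-based species
    assignment against type isolates with neighbour-joining trees, fixed-clock
    conversion of node heights to divergence dates, and a synthetic-data
    generator for a diverged four-species complex so the whole pipeline is
    testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    ape,
    BiocGenerics,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
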