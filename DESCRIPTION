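Package: ibmd
Title: Information-Based Measure of Disagreement for Multiple Observers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates inter-observer disagreement on non-negative ratio
    scales with the information-based measure of disagreement (IBMD),
    generalized to an arbitrary and possibly varying number of observers per
    case, so that rating tables with missing observers remain usable. Provides
    nonparametric case-level bootstrap percentile confidence intervals, a
    two-population comparison workflow based on interval overlap, classical
    comparators (two-way random-effects intraclass correlation for absolute
    agreement, Lin's concordance correlation coefficient, Bland-Altman limits
    of agreement), readers and writers for wide and long rating-table CSV
    files, packaged example datasets (gymnastics judging scores and maternal
    heart rate baseline estimates), a synthetic rating-table generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
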