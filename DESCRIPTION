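Package: readguide
Title: Computer-Guided Reading Assessment, Guidance Scheduling and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying simultaneous letter recognition and
    computer-guided reading in poor readers. Implements an adaptive
    staircase that titrates pseudoword length and presentation time to a
    95 percent recognition criterion, letter-level response scoring by
    minimal edit alignment, a guidance engine that segments text into
    span-sized pieces and schedules fixations, tones and speech windows,
    a synthetic-reader simulator based on temporal summation of letter
    information, and the statistical layer (pooled-SD standardized mean
    differences, exact Wilcoxon tests, Holm step-down correction) used
    to analyse crossover reading experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
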