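Package: serialorder
Title: Decomposing Implicit Serial-Order Knowledge in Serial Reaction Time Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how implicit knowledge of serial order is
    represented in serial reaction time (SRT) tasks. Generates the full trial
    structure of a three-session visual-search SRT experiment with derived-list
    transfer blocks that isolate serial position-item associations
    (ordinal-only trials) from item-item associations (order-only trials);
    simulates reaction times from a two-source learning model under either an
    independent-race or a coactivation architecture; applies median-based
    preprocessing and condition difference scores; tests the race model
    inequality on per-participant CDF percentile points with restricted-range
    correction; and scores post-experiment verbal reports against exact and
    Monte-Carlo guessing nulls. Includes the repeated-measures ANOVA,
    regression, correlation, and within-subject standard-error routines needed
    for the accompanying analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
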