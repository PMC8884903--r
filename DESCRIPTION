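Package: crisprmet
Title: In Vivo Pooled CRISPR Knockout Screen Analysis for Metastasis-Suppressor Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide pooled CRISPR knockout screens of
    tumor metastasis suppressors in vivo: sgRNA quantification from sequencing
    reads, read-count enrichment filtering into per-sample gene presence calls,
    compartment (preimplant, primary, recurrent, blood, metastasis) and
    per-organ gene-set intersection with ubiquity scoring, appearance-frequency
    ranking with OncoPrint-style matrix export, and a human candidate-suppressor
    catalog combining tumor-vs-normal expression tests with median-split
    log-rank survival stratification. Includes stochastic simulators of the
    bottlenecked in vivo screen and of a patient expression/survival cohort,
    with planted ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
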