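Package: pvsignal
Title: Disproportionality-Based Signal Detection for Spontaneous
    Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds drug-event two-by-two contingency tables from
    individual case safety reports (ICSRs), computes the proportional
    reporting ratio (PRR), reporting odds ratio (ROR) and Bayesian
    information component with its 95% credibility lower bound (IC025),
    applies a composite signal criterion, rolls signals up a MedDRA-like
    preferred-term to system-organ-class hierarchy, summarises report
    demographics, and renders signal counts per organ class as a
    squarified treemap. Ships a synthetic spontaneous-reporting-database
    generator with planted drug-event associations so every stage of the
    pipeline can be validated against known ground truth without access
    to a restricted pharmacovigilance database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
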