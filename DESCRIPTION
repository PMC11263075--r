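Package: pvpd
Title: Pharmacovigilance-Pharmacodynamic Signal Analysis for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disproportionality signal detection (reporting odds ratio and
    information component) for drug-event pairs in spontaneous adverse-event
    report databases, applied to antipsychotic-associated sexual dysfunction.
    Includes a seedable synthetic report-stream generator with a closed-form
    reporting-odds-ratio oracle for planted associations, receptor-occupancy
    estimation from binding constants and unbound therapeutic concentrations,
    univariate regression of per-drug median signal strength on per-receptor
    occupancy with activity-signed, pKi and term-exclusion sensitivity
    variants, notoriety-bias time-window sensitivity analyses, and an
    end-to-end pipeline writing all result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
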