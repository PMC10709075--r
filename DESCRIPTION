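Package: pancreg
Title: Cohort Decision Model for Regionalization of Pancreatic Cancer Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic cohort decision model predicting 30-day deaths,
    complications, and complication costs of pancreatic cancer surgery in
    California under the observed distribution of cases across high- and
    low-volume centers versus complete or partial regionalization. Includes
    the published baseline parameter set and literature ranges, named policy
    scenarios (partial regionalization, differential complication costs,
    widened complication-rate gap), one-way deterministic sensitivity sweeps,
    threshold analysis, seeded probabilistic sensitivity analysis over the
    literature ranges, a flat-file parameter config format, and a report
    writer mirroring the published output table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
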