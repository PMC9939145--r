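Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for pharmacovigilance signal detection on
    spontaneous adverse-event report databases distributed in the FAERS
    quarterly ASCII dialect. Reads the DEMO/DRUG/REAC/OUTC/THER/INDI tables,
    deduplicates case versions following the FDA-recommended rules, extracts
    a primary-suspect drug cohort with MedDRA-style PT/SOC event mapping,
    computes four disproportionality statistics (reporting odds ratio,
    proportional reporting ratio, information component, empirical Bayes
    geometric mean) with interval bounds and a joint four-criteria signal
    rule, and summarises time-to-onset and fatal-outcome proportions. A
    synthetic report generator with known ground truth supports fully
    offline testing and calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
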