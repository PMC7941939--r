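Package: eprlink
Title: Data Management Pipeline for Multi-Site Electronic Patient Record Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing routinely collected electronic patient record
    (EPR) extracts in multi-site maternity and perinatal studies:
    pseudonymisation with a check-character study identifier, deterministic
    linkage of neonatal, ultrasound and hospital-activity records onto a
    maternity spine, dictionary-driven harmonisation with a replayable audit
    trail, staged data-quality checklists with a clinician-consensus outlier
    policy, and multiple imputation by chained equations with within- and
    across-cluster scoping. A synthetic multi-site EPR generator with known
    ground truth makes every stage testable without access to real hospital
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    lubridate,
    openssl,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    nnet
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr,
    readxl,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
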