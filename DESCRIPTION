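Package: earlyphase
Title: Design and Analysis Toolkit for Early-Phase Oncology Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact evaluation and search of Simon two-stage designs, a rule
    engine and Monte Carlo simulator for 3+3 dose escalation gated by
    PET-derived receptor-occupancy criteria, RECIST-style best-overall-response
    derivation with exact Clopper-Pearson confidence intervals,
    noncompartmental pharmacokinetic analysis, concentration-occupancy Emax
    modelling, and longitudinal circulating-tumor-DNA and
    immunohistochemistry biomarker summaries. Includes a seeded synthetic
    patient-level data generator calibrated to the operating characteristics
    of a first-in-human selective estrogen receptor degrader study, so that
    every analysis stage can be exercised end to end without access to
    restricted trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
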