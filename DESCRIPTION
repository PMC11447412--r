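Package: keapsense
Title: Dimer-Inactivation Inference and Sensor-Variant Screening for KEAP1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative tools for studying how the KEAP1 homodimer senses
    oxidative stress. Fits a log-log calibration curve relating graded KEAP1
    protein dosage to NRF2 target-gene induction and inverts it, with
    bootstrap confidence intervals, to estimate residual KEAP1 activity from
    observed mRNA levels. Implements a random-dimerization population model
    with closed-form predictions of total E3-ligase activity under the
    competing monomer-inactivation and dimer-inactivation hypotheses, and
    selects the hypothesis consistent with the estimated activity. Also
    classifies KEAP1 protein variants against the oxidative and electrophile
    sensor-cysteine maps, evaluates the fail-safe disulfide-pair redundancy,
    and predicts responsiveness to the four classes of NRF2 inducers.
    Includes a seeded synthetic-data generator emulating graded-dosage
    calibration series, stress-cohort measurements and variant tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
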