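Package: nsablate
Title: Electro-Thermal Simulation and Lethal-Threshold Calibration for
    Temperature-Controlled Nanosecond-Pulse Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric finite-element model of a single internally cooled
    needle electrode with a grounding pad, as used in temperature-controlled
    nanosecond-pulse irreversible electroporation of liver tissue. Solves the
    quasi-static current-continuity problem on graded, field-adaptively refined
    triangular meshes, drives a transient Joule-heating bioheat solver with a
    duty-cycle temperature-feedback controller, and calibrates lethal
    electric-field thresholds by matching measured ablation volumes to simulated
    volume-above-field curves. Includes group statistics (Welch's t-test, linear
    trends) and a truncated-normal synthetic-cohort generator so the calibration
    and statistics stages are fully testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
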