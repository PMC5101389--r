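Package: chromdoe
Title: Design of Experiments, PLS Response-Surface Modelling and ICH
    Validation for HILIC Method Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for chemometric development of liquid-chromatography
    methods: rotatable central composite designs with coded/actual factor
    conversion, PLS1 (NIPALS) response-surface models with leave-one-out
    Q2 and jackknife coefficient confidence intervals, constraint-based
    selection of separation conditions, and the ICH Q2(R1) validation
    battery (linearity with intercept significance, signal-to-noise
    LOD/LOQ, accuracy, precision, one-factor-at-a-time robustness,
    selectivity and tablet assay). Includes a calibrated synthetic HILIC
    retention simulator for moxonidine and its four pharmacopoeial
    impurities that reproduces the critical coelution/resolution
    behaviour of the published separation, used as ground truth for
    end-to-end in-silico studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
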