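Package: ebgtools
Title: Electrobulbogram Time-Frequency Analysis and Group Biomarker Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electrobulbogram (EBG) recordings of human
    olfactory bulb activity: epoching and mastoid re-referencing, power-line
    notch filtering, Hilbert-envelope artifact screening, EOG regression-based
    ocular correction, frequency-adaptive multitaper (DPSS) time-frequency
    decomposition, separation of induced from phase-locked oscillatory power,
    odor-versus-sniff contrasts, cluster-based Monte Carlo permutation tests of
    group differences, component scoring with ICC(2,k) reliability, and
    mixed-effect logistic/linear models for diagnostic classification and
    clinical associations. Includes a seeded synthetic-data generator that
    emulates the recording and cohort structure of a two-group olfactory
    electrophysiology study for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
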