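Package: traumasim
Title: Virtual Trauma Patient Simulation and ATLS Performance Analytics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable discrete-time virtual-patient engine for trauma
    training scenarios, centred on the primary survey of a pelvic trauma
    case. Provides trainer-editable scenario files (YAML/JSON) with
    validation, a linear-deterioration patient model calibrated to a
    configured remaining lifetime with hemorrhage-coupled vital signs, an
    ATLS primary-survey reference grammar whose enumeration yields the
    valid ABCDE treatment sequences, session event logging with automatic
    report generation, performance scoring by longest-common-subsequence
    against the reference set, cohort-level descriptive statistics and
    Wilcoxon rank-sum comparisons, seven-point Likert questionnaire
    summaries, and a seeded synthetic trainee-behavior generator that
    emulates student and doctor cohorts for end-to-end evaluation without
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
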