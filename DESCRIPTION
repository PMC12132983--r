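Package: signgaps
Title: Detecting Clinical Skill Gaps from Digital Consultation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify potential clinical skill gaps of healthcare
    workers from the numeric clinical signs recorded by a digital clinical
    decision support tool during outpatient paediatric consultations.
    Provides a synthetic multi-facility consultation cohort generator with
    injectable measurement behaviours, an LMS growth-reference z-score
    engine, per-facility summary statistics (missingness, modal value
    frequencies, median, IQR, extreme z-score fractions), a rule-based
    pattern classifier (skipper, mono-repeater, multi-repeater, wrongly
    evaluated) with three severity levels against a pooled all-facility
    reference, a facility selection rule, and descriptive analysis of
    prospectively observed sign assessments (performed/skipped, quality,
    multi-select reasons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
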