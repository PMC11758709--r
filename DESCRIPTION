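Package: schedcomplex
Title: Scheduling Complexity Metrics for Patient Appointment Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-patient scheduling complexity from appointment-level
    scheduling records. Scheduling complexity aggregates three components by
    harmonic mean: sequence complexity (appointments scheduled and arrived to
    out of first-in-first-out order), resolution complexity (cancellations and
    no-shows whose action date does not co-occur with another scheduling
    action), and location complexity (attended dates spanning two or more care
    locations). Also provides count-based comparator ratios and their
    harmonic-mean composite, quartile low/medium/high stratification with
    Pearson chi-square comparison of stratifications, needs-association
    tables, a seeded synthetic cohort generator for testing every stage
    without patient data, and a small pipeline (simulate, compute, compare)
    with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
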