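Package: kanosight
Title: Kano Survey Evaluation and In-Line-of-Sight Prioritization of
    Quality Attributes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating paired functional/dysfunctional (Kano)
    questionnaires: per-respondent answer-pair categorization, the
    classical mode and if-then category-assignment rules, Timko
    satisfaction (Better) and dissatisfaction (Worse) indices with
    optional importance weighting from self-stated relevance, and an
    "in-line-of-sight" prioritization that ranks attributes by Euclidean
    distance and angle relative to a chosen quadrant corner of the
    Better-Worse plane. Includes validated CSV ingestion of survey
    panels (long and wide layouts), reproducible group splitting and
    stratification, Pearson chi-square group comparisons, a calibrated
    multinomial generator of synthetic survey panels, quadrant plotting,
    and a bundled reference table of category counts from a two-group
    physician survey on nine health-app quality principles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
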