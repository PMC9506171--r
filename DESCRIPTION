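Package: navscrew
Title: Three-Dimensional Planned-Versus-Actual Accuracy Analysis for
    Navigated Pedicle Screw Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the accuracy of image-guided (CT-navigated) pedicle
    screw placement against an intraoperative trajectory plan. Provides
    frame-tagged 3D geometry (points, unit vectors, proper rigid transforms),
    landmark-based rigid co-registration with fiducial and target registration
    error metrics and a per-level verification/exclusion rule, per-screw
    deviation metrics (Euclidean head/tip point distances and angular
    trajectory deviation), a geometric Gertzbein-Robbins grading surrogate
    (maximum cortical breach of a screw cylinder outside an elliptical pedicle
    corridor), the accompanying statistical battery (pooled/Welch t, one-way
    ANOVA with Holm-Sidak step-down post-tests, Pearson chi-square,
    Kruskal-Wallis), and a seeded synthetic cohort generator calibrated to
    published accuracy benchmarks for lumbosacral instrumentation so the full
    pipeline is testable without patient imaging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
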