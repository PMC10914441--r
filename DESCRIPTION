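Package: brainchart
Title: Lifespan Brain Charts and Atrophy Staging from Cross-Sectional
    Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits normative lifespan trajectories ("brain charts") of
    brain-structure volumes from cross-sectional volumetric tables,
    fits matching disease trajectories constrained over the whole
    lifespan by combining patients with younger controls, detects the
    age at which the healthy and disease 95% confidence bands stop
    overlapping, and orders the divergences into an anatomical staging
    timeline of atrophy progression. Includes preprocessing
    (left/right summation, normalization to total intracranial volume,
    z-scoring, Kolmogorov-Smirnov normality checks, model-outlier
    flagging), polynomial model selection by significance gates and
    BIC, a synthetic multi-cohort generator with known ground truth,
    and a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
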