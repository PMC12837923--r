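Package: catpattern
Title: Human and Machine Categorisation Analysis with Ordinal Performance Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing human and machine image-categorisation
    behaviour from trial-level response tables: accuracy aggregation,
    chance-corrected trial-by-trial agreement (Cohen's kappa with
    large-sample confidence intervals and Landis-Koch bands), default
    Jeffreys-Zellner-Siow Bayes-factor t tests for accuracy comparisons,
    and an individual-level ordinal-discretisation framework that reduces
    per-category accuracy profiles to qualitative pairwise patterns,
    enumerates them across a cohort, and matches model patterns to the
    modal human pattern. Includes a synthetic-cohort generator with
    latent accuracy subgroups, structured confusions and test-retest
    stability, plus counterbalanced experiment-schedule construction,
    so the full pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
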