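Package: connpattern
Title: Longitudinal Resting-State Connectivity-Pattern Analysis
Version: 0.1.0
Authors@R: person("Connectivity", "Analyst", email = "analyst@example.org",
    role = c("aut", "cre"))
Description: Multivariate analysis of resting-state functional connectivity
    patterns between sensorimotor cortical areas, designed for longitudinal
    stroke-recovery cohorts. Builds Fisher-Z ROI-pair connectivity patterns
    from BOLD time series, tests group differences with a Euclidean-distance
    permutation test, bounds undetected effects with a permutation-based
    equivalence test using injected ground-truth patterns, quantifies
    within-group pattern variability, computes split-half reliability, and
    derives the relative interhemispheric connectivity (RelCon) metric from
    voxel-level series. Includes a synthetic-cohort generator with a
    positive-definite ground-truth connectivity structure, multivariate AR(1)
    temporal noise, idiosyncratic subject perturbation, injectable group
    differences, and session missingness, for power analysis and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
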