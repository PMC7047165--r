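Package: keelbone
Title: Radiographic Quantification of Keel Bone Damage in Laying Hens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying keel bone damage from lateral radiographs
    of laying hens: aluminium step-wedge calibration of gray values to
    millimetres of aluminium equivalent, polygon-based scoring of keel
    deviations (proportion of deviated area, POD) and radiographic density
    with exclusion regions, longitudinal cohort aggregation (period means,
    assay coefficients of variation, transponder-based activity rates,
    prevalence tables), time-to-first-damage survival datasets and
    proportional-hazards fits with pen clustering, and line-by-treatment-by-
    period linear mixed models. A synthetic phantom-radiograph and cohort
    generator with known ground truth makes every stage testable without
    access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    nlme,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
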