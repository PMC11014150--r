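Package: madape
Title: Posture and Physical-Activity Intensity from Hip-Worn Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for raw hip-worn triaxial accelerometer
    recordings. Computes mean amplitude deviation (MAD and MADxyz) intensity
    features in 6 s epochs, converts them to metabolic equivalents (MET) with a
    piecewise linear regression, recognizes walking epochs to maintain an
    upright reference vector, and derives the angle for posture estimation
    (APE) to classify stationary behavior into standing, sitting, reclining and
    lying. Includes a device trigger/quiescence emulator for non-wear
    detection, day-validity and participant-inclusion rules, MET and APE
    histogram summaries, hour-by-hour stationary profiles, cohort-level
    statistics (sex-specific fitness tertiles, BMI categories, age-sex
    weighting, partial Spearman correlations, Kruskal-Wallis with Dunn's
    post-hoc test), and a synthetic signal generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
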