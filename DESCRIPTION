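Package: hipmetrics
Title: Radiographic Measurement of Hip Implant Orientation and Leg Length
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Landmark-driven measurement of acetabular component position and
    leg length on anteroposterior pelvic radiographs after total hip
    arthroplasty. An ellipse is fitted to annotated cup-face rim points by
    direct least squares; radiographic anteversion is the arcsine of the
    minor-to-major axis ratio, inclination is the angle between the major
    axis and the inter-ischial reference line, and leg length is the
    calibrated perpendicular distance from that line to a trochanter
    landmark. Includes the method-comparison and reliability statistics used
    to validate such measurement software (replicate averaging, paired
    differences, within-threshold proportions, chi-square/Fisher tests, and
    pooled intraclass correlation coefficients), a synthetic-annotation
    simulator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
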