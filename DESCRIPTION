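Package: sfmaps
Title: Spatial Frequency Maps in Human Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling population spatial-frequency tuning across
    human retinotopic maps (V1-V3) measured with fMRI. Synthesizes log-polar
    "scaled grating" stimuli and their local spatial-frequency and orientation
    fields; fits one-dimensional log-Gaussian tuning curves to
    eccentricity-binned responses; fits a compact nine-parameter model of
    preferred spatial period and response gain across an entire visual-field
    map using a precision-weighted, L2-normalized loss and a first-order
    (Adam) optimizer; and aggregates per-subject estimates into cohort
    summaries with precision-weighted means and bootstrapped 68% confidence
    intervals. Includes a synthetic-cohort generator (pRF layouts plus
    trial-level heteroscedastic betas) so the full pipeline can be exercised
    end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
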