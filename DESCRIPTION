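Package: corticoflow
Title: Synthetic Widefield Imaging Cohorts and Visuomotor Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for widefield calcium imaging of
    mouse dorsal cortex under closed-loop and open-loop visuomotor conditions.
    Generates synthetic cohorts of mice and 5-minute recording sessions with
    known ground truth (bout-structured locomotion, visual-flow coupling,
    1-second visuomotor mismatches, spatially structured latent factors, and a
    treatment transform that scales long-range latent coupling), and implements
    the matching analysis chain: median-normalized dF/F with running-percentile
    drift correction, session-level seizure quality control, locomotion and
    visual-flow onset detection, baseline-subtracted event-triggered averages
    with hierarchical-bootstrap confidence bands, closed/open-loop response
    similarity, distance-resolved inter-areal correlation density maps, and
    short- versus long-range treatment-induced correlation changes with
    rank-sum and bootstrap inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
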