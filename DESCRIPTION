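Package: fixstab
Title: Fixation Instability Scoring from Eye-Tracker Pupil-Center Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intraoperative fixation instability from the
    pupil-center position plots produced by excimer-laser eye trackers.
    Detects the blue position marks on the 6 x 6 mm tracking grid, extracts
    connected mark clusters, and computes three plot morphometrics -- sum
    area (SA), sum perimeter (SP) and average centroid deviation (ACD) --
    which combine linearly into a Fixation Instability Score (FIS) on a
    0-90 scale with normal / borderline / case anxiety bands. Includes
    Hospital Anxiety and Depression Scale (HADS) anxiety sub-score scoring,
    a class-conditional synthetic-cohort generator with analytic ground
    truth, an evaluation suite (per-parameter maximum-margin classifiers,
    one-vs-one ROC with Hanley-McNeil standard errors, DeLong paired AUC
    comparison, Youden-index cutoff selection, Spearman correlation
    matrices), class-wise average position maps with optional PCA
    denoising, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    e1071,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
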