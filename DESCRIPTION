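Package: spatempRSA
Title: Spatiotemporal Representational Similarity Analysis with
    Cross-Validated Mahalanobis Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissociating kinematic from muscle encoding in motor
    cortex with multivariate pattern analysis. Builds kinematic, muscle and
    ethological model representational dissimilarity matrices (RDMs) from
    multi-channel recordings (data glove, EMG); computes cross-validated
    Mahalanobis (crossnobis) distances with multivariate noise
    normalization; runs surface-based searchlight RSA with omnibus
    (max-statistic) permutation thresholds, group heatmaps and
    Wilcoxon/FDR model contrasts; and runs sliding-window temporal RSA on
    band-filtered source time series with cluster-based permutation
    inference and noise ceilings. Includes synthetic-data generators that
    plant a known representational geometry into glove, EMG, fMRI-like
    surface and MEG-like source data so that every stage of the pipeline
    can be validated by parameter recovery.
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
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
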