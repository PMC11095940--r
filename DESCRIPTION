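Package: AxonValence
Title: Valence-Preference Analysis of Single Dopamine Axon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-photon calcium imaging of single
    mesocortical dopamine axons during reward/aversive classical
    conditioning. Computes sliding-percentile dF/F traces, collapses
    duplicated ROIs onto axons by iterative correlation clustering,
    quantifies event-triggered responses with signed-rank significance,
    derives polar-angle valence preference with k-means clustering and
    circular statistics, detects anticipatory licking and locomotion,
    and decodes trial-by-trial cue discrimination with a class-balanced
    tree ensemble under stratified cross-validation. Includes a seeded
    synthetic-session generator with ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    signal,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
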