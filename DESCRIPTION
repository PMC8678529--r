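Package: swayclust
Title: Clustering of Quiet-Standing Postural Sway from Marker Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for evaluating post-stroke quiet-standing
    postural sway from multivariate motion-capture marker trajectories.
    Recordings of 10 body markers plus the center of mass (33 kinematic
    variables) are offset to the ankle midpoint, scaled by body-segment
    lengths, low-pass filtered with a zero-phase Butterworth filter, and cut
    into fixed-length data slots. Slots are clustered by dynamic time warping
    with partition-around-medoids (DTW-PAM) or DTW barycenter averaging
    (DTW-DBA); the slot length and cluster count are selected on a grid by the
    Davies-Bouldin, Calinski-Harabasz and Dunn validity indices. Per-slot sway
    features (amplitude, standard deviation, dominant sway frequency) are
    compared between clusters with normality/homogeneity-gated post-hoc tests
    (Tukey-Kramer or pairwise Wilcoxon with Benjamini-Hochberg adjustment),
    and cluster membership is tabulated against days after stroke onset. A
    synthetic cohort generator with planted cluster structure makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
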