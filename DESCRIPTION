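Package: mobidt
Title: Dual-Task Mobile Brain/Body Imaging Analysis of Go/NoGo Performance,
    Gait Variability and Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for dual-task (sitting versus treadmill-walking)
    mobile brain/body imaging experiments built around a Go/NoGo response
    inhibition task. Implements behavioral scoring (response-time gating,
    trial-outcome classification, d-prime sensitivity with edge correction),
    stride-to-stride gait variability from 3D heel-marker trajectories via
    dynamic time warping, ERP preprocessing (zero-phase Chebyshev Type II
    filtering, bad-channel detection, spherical-spline interpolation, average
    reference, epoching, baseline correction, artifact-based epoch rejection,
    condition averaging), spatiotemporal cluster-based permutation statistics
    with the weighted cluster mass statistic, scalar statistics
    (normality-gated paired tests, Wilcoxon signed rank, mixed 2x2 ANOVA,
    improver classification against a cohort null) and combined two-stage
    Benjamini-Krieger-Yekutieli false discovery rate control. A synthetic
    cohort generator emulates all three data streams so the full pipeline is
    testable end to end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
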