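Package: cwtwin
Title: Cognitive Workload Digital Twin for First Responders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for near-real-time assessment of a first responder's
    cognitive workload from demographic, psychological, and wearable
    physiological data. Provides a synthetic cohort generator (structural
    path model over HEXACO personality domains plus labelled 1 Hz
    GSR/HR/RR/temperature recordings), signal preprocessing and windowed
    feature extraction, per-sensor probabilistic Load/Rest classifiers fused
    by averaging, equation-wise path-coefficient estimation with chi-square
    fit assessment, a discrete Bayesian causal network with exact
    variable-elimination inference under hard and soft (virtual) evidence,
    and a perception-action monitoring loop that tracks workload on a 1-5
    scale and renders operator reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
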