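Package: immunonoise
Title: Residual-Subspace Anomaly Detection in Immunologic Biomarker Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects hidden random fluctuations ("noise") in panels of
    immunologic biomarkers from periodontitis patient cohorts.  Provides a
    reproducible pipeline that standardizes a patient-by-parameter table,
    identifies the residual principal-component subspace of the parameter
    correlation matrix, screens residual parameters for anomalies with a
    plug-in (Shannon) sample-entropy statistic, cross-checks candidates with
    two-step clustering (k-means pre-clustering followed by agglomerative
    merging under the log-likelihood distance) and its predictor-importance
    scores, and classifies early-onset versus late-onset disease with a
    k-nearest-neighbour classifier built on aggregate Local Outlier Factor
    scores.  A calibrated synthetic-cohort generator with an explicit
    contamination model makes every stage testable without access to the
    original patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
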