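Package: glocr
Title: Explainable OCT-Based Glaucoma Staging and Likelihood Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for diagnosing and staging glaucoma from optical coherence
    tomography (OCT) summary data. Extracts spatial-domain (quadrant, clock-hour,
    distributional and information-theoretic) and frequency-domain (periodogram,
    Welch, discrete-wavelet, harmonic-slope, spectral-entropy) features from
    256-point circumpapillary RNFL TSNIT thickness profiles together with
    GC-IPL and macular thickness summaries; imputes artefact-masked parameter
    groups by chained equations; balances classes by minority interpolation;
    selects features by correlation pruning and ANOVA F scores; trains tuned
    KNN, RBF-SVM and random-forest staging classifiers under patient-level
    cross-validation; explains them with exact and sampled Shapley values,
    partial-dependence and ICE curves, and decision-boundary cut-offs; and
    combines the explanations into a major/minor-criteria glaucoma likelihood
    calculator. A seeded synthetic cohort generator emulating stage-conditioned
    double-hump TSNIT morphology makes every stage testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
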