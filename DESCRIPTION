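Package: irapfast
Title: Scoring and Group Inference for Latency-Based Implicit Measures (IRAP and FAST)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for scoring and analysing two latency-based implicit
    measures of learning history: the Implicit Relational Assessment
    Procedure (IRAP) and the Function Acquisition Speed Test (FAST),
    together with the Klein Sexual Orientation Grid (KSOG) self-report.
    Implements the D-score algorithm for IRAP trial-level latencies
    (practice-criterion gate, trial and participant exclusion rules,
    per-pair per-trial-type standardised difference scores), cumulative-
    record learning-slope scoring for the FAST, a two-group comparison
    battery (Wilcoxon rank-sum with a W/(n1*n2) effect-size estimator,
    Cliff's delta, Vargha-Delaney A, Welch t with Cohen's d, balanced
    split-plot ANOVA with Tukey/Bonferroni contrasts, Spearman
    correlations), ROC curves with DeLong variance and curve comparison
    tests, analytic power-sensitivity (minimal detectable effect)
    computations, and a calibrated trial-level cohort simulator so the
    whole pipeline can be exercised without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    lme4,
    lmerTest,
    emmeans
Config/testthat/edition: 3
RoxygenNote: 7.3.3
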