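Package: fetalph
Title: Predicting Fetal Acid-Base Status from Intrapartum Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intrapartum fetal heart rate (FHR) recordings and
    predicting umbilical-cord blood pH class at delivery. The pipeline cleans
    beat-per-minute series (three-sigma outlier band and post-delivery noise-run
    removal), partitions beats into parasympathetic (downward) and sympathetic
    (non-downward) components, quantifies heart-rate-variability complexity with
    approximate entropy, encodes beat-to-beat dynamics into an eight-symbol
    alphabet, and trains a four-hidden-state discrete hidden Markov model
    (Baum-Welch training, Viterbi decoding) whose states correspond to clinically
    defined cord-pH intervals. Includes multiclass evaluation (confusion matrices,
    per-class sensitivity/specificity/precision/F1), balanced-cohort resampling,
    and a synthetic cohort generator emulating intrapartum traces for testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
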