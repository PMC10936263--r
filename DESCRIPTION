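Package: exofatigue
Title: EMG-Based Muscle Fatigue Risk Assessment for Occupational
    Exoskeleton Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Processes multi-channel surface electromyography (EMG)
    recordings from occupational field studies into localized muscle
    fatigue risk estimates, and compares paired with/without-exoskeleton
    conditions. Implements the linear-envelope chain (spike removal,
    zero-lag Butterworth band-pass, rectification, low-pass envelope),
    normalization to maximum voluntary isometric contraction (MVIC)
    references, duty-cycle computation against an activity threshold,
    threshold limit values (TLV) for localized muscle fatigue as a
    decreasing function of duty cycle, fatigue risk values, exoskeleton
    benefit categorization, and a paired cohort statistics stage
    (Lilliefors normality gate, paired t-test or exact Wilcoxon
    signed-rank test, Cohen's d, confidence intervals). A seeded
    synthetic EMG generator produces cyclic assembly-task recordings
    and MVIC trials with analytically known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    nortest,
    signal,
    stats,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
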