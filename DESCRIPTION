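Package: vorlearn
Title: Quantification of Vestibulo-Ocular and Optokinetic Reflex Learning
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures oculomotor learning from raw eye-position recordings.
    Eye position is low-pass filtered and differentiated with a
    Savitzky-Golay filter, eye velocity is fit with a fixed-frequency
    sinusoid, saccades and movement artifacts are excluded by residual
    thresholding with temporal padding and segment filtering, and a second
    fit on the retained samples yields the response amplitude and gain for
    each vestibulo-ocular reflex (VOR) or optokinetic reflex (OKR) test.
    Per-test measurements are aggregated into block summaries and
    percent-change learning curves, and compared across groups with
    repeated-measures ANOVA, Tukey contrasts and t-tests.  A synthetic
    trace and cohort generator with known ground truth supports
    end-to-end parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    emmeans,
    graphics,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
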