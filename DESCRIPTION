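Package: latdiff
Title: Estimating Audiovisual Differences in Perceptual Latency from
    Temporal Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the difference in perceptual latency
    between an auditory and a visual stimulus from three psychophysical
    tasks: temporal order judgments, simultaneity judgments and
    two-interval duration judgments.  Provides synthetic observers for the
    method of constant stimuli, maximum-likelihood fitting of the three
    psychometric-function families (four-parameter cumulative normal,
    scaled Gaussian, two-parameter cumulative normal), latency-difference
    estimators including the duration-based estimator that cancels the
    time-order error, exact Clopper-Pearson binomial intervals, parametric
    bootstrap confidence intervals, and a cross-task consistency battery
    (correlations with bootstrap intervals, t tests, and the
    confidence-interval non-overlap criterion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
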