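Package: ugm
Title: Unit Gamma Measurement Estimation of the Number of True Null Hypotheses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the number of true null hypotheses (m0) in large-scale
    multiple testing by the Unit Gamma Measurement (UGM) method, which
    partitions the p-value axis into intervals of length gamma and combines
    the per-interval counts above gamma into a harmonic-mean estimate of the
    null density per unit length.  Also provides the Storey lambda, adaptive
    Benjamini-Hochberg and two-stage comparator estimators, the adaptive
    linear step-up false discovery rate procedure with m0-based adjusted
    p-values, vectorised per-gene two-sample t-tests (pooled and
    Welch-Satterthwaite) for expression matrices, and a Monte-Carlo benchmark
    that simulates two-group expression profiles and summarises estimator
    bias, dispersion and root-mean-square error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
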