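Package: covgof
Title: Goodness-of-Fit Testing for Covariance Functions of Functional Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether a parametric covariance function is adequate for
    repeated-measures data, against a smooth nonparametric alternative.  The
    primary null model is the quadratic-polynomial covariance induced by a
    linear random intercept and slope model; the alternative covariance is
    estimated by symmetric tensor-product cubic B-spline least squares on
    off-diagonal cross-products.  The test statistic is the squared
    Hilbert-Schmidt distance between the smoothed alternative and the
    smoothed parametric null surface, with a wild (parametric) bootstrap
    null distribution.  Also provides the competing restricted likelihood
    ratio test of a zero quadratic random-effect variance, a synthetic data
    generator for irregular longitudinal designs, and a simulation harness
    for size and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    parallel,
    splines,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
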