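Package: gkequate
Title: Gaussian Kernel Equating with Bandwidth-Aware Standard Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel equipercentile equating of test forms under the
    equivalent-groups design. Discrete score distributions are presmoothed
    either as raw multinomials or with a two-parameter logistic item
    response model fitted by marginal maximum likelihood (EM), continuized
    with a Gaussian kernel whose bandwidth minimizes the PEN1 penalty, and
    equated via the equipercentile function. Analytic standard errors of
    equating are provided both in the classical delta-method form that
    treats the bandwidths as fixed and in a modified form that propagates
    the sampling variability of the penalty-minimizing bandwidth estimator
    through the implicit function theorem. A Monte Carlo harness reproduces
    the full pipeline across replications and reports analytic versus
    empirical standard errors and confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
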