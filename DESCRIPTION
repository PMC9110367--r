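Package: edgenull
Title: Edge-Centric Functional Connectivity and Its Static Gaussian Null Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes edge-centric functional-connectivity measures from
    parcellated BOLD time series (edge time series, edge functional
    connectivity, cofluctuation root-sum-of-squares, binary edge series,
    edge communities, and seed-based coactivation summaries) together with
    their analytic predictions under a static null model of i.i.d.
    multivariate Gaussian frames whose covariance matches the node
    functional connectivity. The null distribution of the cofluctuation
    amplitude is a mixture of Gamma components set by the eigenvalues of
    the node correlation matrix; the package evaluates its moments,
    moment-generating function and CDF (by characteristic-function
    inversion), and tests empirical series against it with a
    Kolmogorov-Smirnov test. A surrogate generator realises the null model
    (and temporally autocorrelated contrasts) so every prediction can be
    verified on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
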