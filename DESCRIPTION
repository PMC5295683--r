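Package: coaltimes
Title: Coalescence Time Distributions and Site-Frequency Spectra for Large
    Samples under Time-Varying Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact and approximate coalescence computations for samples of
    arbitrary size drawn from populations with deterministic size histories.
    Provides marginal densities of coalescence times by numerical inversion
    of the coalescent characteristic-function transform (adaptive
    Gauss-Kronrod quadrature and FFT paths), the closed-form limit density
    of the time to the most recent common ancestor, numerically stable
    expectations of tree height, total branch length and the expected allele
    frequency spectrum valid for sample sizes into the hundreds of
    thousands, large-sample closed-form approximations with relative-error
    reports, maximum-likelihood fitting of an exponential-growth parameter
    to an observed site-frequency spectrum with parametric-bootstrap
    confidence intervals, and a coalescent simulator under arbitrary
    population-size trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
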