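Package: wfangular
Title: Wright-Fisher Transition Densities in Fisher's Angular Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form heuristic Gaussian approximation to the two-allele
    Wright-Fisher transition probability density under genetic drift,
    selection and mutation, built in Fisher's angular coordinates
    (theta = arccos(1 - 2x)).  On top of the density the package provides
    maximum-likelihood estimation of the effective population size,
    selection coefficient and mutation rates from variant-frequency time
    series, likelihood-ratio selection scans with ROC evaluation, a
    frequency-space Gaussian baseline density for benchmarking, and
    discrete-binomial and Euler-Maruyama Wright-Fisher simulators that
    double as synthetic-data generators and verification oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
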