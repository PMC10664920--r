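Package: netstab
Title: Stability of Layered Recurrent Networks with Transmission Delays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing the linear and nonlinear stability of
    discrete-time layered recurrent networks in which feedforward
    transmission is either delayed by one time step (biological scheme) or
    instantaneous (artificial scheme). Builds feedforward/feedback
    connectivity matrices from declarative network specifications, simulates
    the dynamics, classifies stability from the spectral radius of the
    effective update matrix, evaluates Chebyshev-polynomial unit-circle root
    conditions on characteristic polynomials, traces bifurcation boundaries
    over two-parameter slices, checks the spectral equivalence of the two
    delay schemes for single-distance feedback, and linearizes nonlinear
    dynamics around fixed points for a library of standard activation
    functions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
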