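Package: specfda
Title: Functional and Discrete Chemometric Classification of Raman Spectra
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare functional and discrete (multivariate) data
    analysis regimes for vibrational spectra. Provides a two-class Raman
    spectrum simulator with controllable peak shift, signal-to-noise ratio
    and random polynomial background; clamped B-spline basis systems
    evaluated by the Cox-de Boor recursion; least-squares functional
    approximation with elbow-based selection of the basis size; functional
    principal component analysis solved exactly in coefficient space via the
    basis Gram matrix; discrete principal component analysis; linear
    discriminant analysis on component scores; and a cross-validated
    comparison harness that reports mean sensitivities over a peak-shift by
    signal-to-noise grid together with Kruskal-Wallis significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    MASS,
    splines,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
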