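Package: fbcells
Title: Statistical Fiber-Bundle-Cell Modeling of Tensile Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward computation of the expected tensile force process of
    statistical fiber bundle cells (FBCs) with nonlinear elastic fibers:
    ideal (E), pre-strained or crimped (EH), slipping (ES) and oblique (ET)
    bundles, their weighted parallel composites, damage and reliability maps,
    decomposition of measured force-strain curves into series of nonlinear
    E-bundles, damage-spectrum fitting, and a Monte-Carlo fiber-failure
    oracle.  Includes curve normalization, Fourier-descriptor extraction with
    a nearest-neighbour learning database for fit initialization, bounded
    least-squares model fitting, synthetic fixture generation, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
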