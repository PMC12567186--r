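Package: bdsfit
Title: Broadband Dielectric Spectroscopy Analysis of Relaxations in Polymer Films
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing broadband dielectric spectroscopy (BDS) of
    semicrystalline biopolymer films such as solution-cast chitosan.
    Implements multi-process Havriliak-Negami plus fractional-exponent
    conductivity modelling of complex permittivity, per-isotherm least-squares
    fitting of the dielectric loss and thickness-invariant global fitting of
    the loss tangent, relaxation-map construction, Arrhenius and
    Vogel-Fulcher-Tammann temperature-law fits with derived glass-transition
    temperatures and dynamic fragility, two-regime dc-conductivity analysis,
    and Maxwell-Wagner-Sillars interfacial-polarization times.  A synthetic
    spectra generator with known ground truth (including measurement noise and
    sample-thinning drift) supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
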