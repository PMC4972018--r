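Package: fragmon
Title: Range Monitoring with Secondary Charged Fragments for Ion-Beam Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for Bragg-peak range verification in particle therapy
    using the charged secondary fragments emitted at large angles from the
    beam path. Provides Bethe-Bloch stopping power and CSDA range
    calculations, analytic phantoms with exact ray tracing and
    water-equivalent path lengths, a fragment-emission Monte Carlo
    calibrated on measured per-primary yields, detector acceptance and
    point-of-closest-approach vertex reconstruction, double-logistic fits
    of longitudinal emission profiles with the Delta40/delta40 range
    observables and their resampling dispersions, and recovery of
    absorption-distorted profiles through thickness-dependent look-up
    tables of fit parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    magrittr,
    rlang,
    minpack.lm,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
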