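Package: seamapr
Title: Degenerate RBS Library Design and Sequence-Expression-Activity Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs minimal degenerate ribosome-binding-site (RBS) libraries
    that uniformly cover a targeted translation-initiation-rate range, using a
    thermodynamic model of bacterial translation initiation and a genetic
    algorithm over the 16-letter IUPAC nucleotide alphabet. Couples the
    sequence-to-expression model with a de-dimensionalized mass-action kinetic
    model of the crtEBI carotenoid pathway to build sequence-expression-activity
    maps (SEAMAPs): kinetic parameter identification from variant productivity
    data, flux control coefficients, transcription-induction response curves,
    precursor-supply sweeps, and evolutionary-landscape simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
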