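Package: petruq
Title: Uncertainty Analysis of Rigid MR-PET Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantifying the precision of
    rigid T1-weighted-MR to PET registration and its propagation into amyloid
    PET quantification. Generates seeded digital brain phantoms with
    early/late-frame amyloid-positive and amyloid-negative tracer
    distributions, simulates list-mode PET data through a parallel-beam
    projector with attenuation, scatter and randoms, bootstrap-resamples the
    event stream at arbitrary count levels, reconstructs with OSEM under
    non-attenuation-corrected, attenuation-corrected and fully quantitative
    modes, performs perturbed rigid registrations driven by normalised mutual
    information, and summarises registration precision as Dice-coefficient
    distributions, Brown-Forsythe equal-variance comparisons, and the
    coefficient of variation of SUVr with and without iterative-Yang partial
    volume correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
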