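Package: polarpath
Title: Depth-Selective Analysis of Backscattered Polarimetric Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploiting the spatial structure of backscattered
    polarized-light images to gain near-surface sampling sensitivity in
    turbid, tissue-like media. Provides a Mie single-scattering engine
    (angular Mueller matrix, scattered Stokes vectors, polar
    polarization-intensity profiles, orthogonalization intervals, number
    densities for a target scattering coefficient), a polarization-tracking
    Monte Carlo simulator of co/cross linear and circular backscatter images
    from microsphere suspensions with per-pixel scattering-event
    bookkeeping, spatial field-selection analysis (scattering-count maps,
    radial profiles, oriented-region Npp metrics, four-lobed pattern
    quantification), and a two-group differentiation pipeline (region
    intensity sums, pooled-deviation t-scores, polarimetric maps) together
    with a synthetic generator of normal versus demineralized polarimetric
    tooth image pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
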