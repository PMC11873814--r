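Package: zonecell
Title: Unit-Cell Determination from Independent Electron Diffraction Zonal Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines three-dimensional unit-cell parameters from a set of
    independent, randomly oriented electron-diffraction zone patterns, each
    reduced to two basis vectors and an inter-vector angle. Implements metric
    plane-symmetry classification of patterns, a symmetry-adapted reciprocal
    grid search over candidate cells ranked by a weighted reliability index,
    zone enumeration and indexing with centring reflection conditions, Delaunay
    cell reduction with conventional-setting detection, basis-vector extraction
    from peak lists (least squares and autocorrelation), and a synthetic
    zonal-pattern generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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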