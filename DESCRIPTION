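Package: seedmorph
Title: Outline Morphometrics of Seed Populations with Elliptic Fourier
    Average Contours, J-Index Similarity and Bezier Curvature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative description and classification of seed
    shape from binary silhouette images or outline (TPS) files. Closed seed
    contours are extracted with sub-pixel precision, described by classical
    shape measurements (area, perimeter, circularity, aspect ratio, roundness,
    solidity) and by elliptic Fourier coefficients (8 harmonics). Normalized
    coefficients are averaged into per-population average contours and into
    reference shape models; populations are scored against models with the
    J-index (percent area overlap after registration maximizing similarity)
    and classified into morphotype groups by threshold rules. The curvature
    signature of the lower seed profile is measured on a least-squares Bezier
    fit. Population comparisons use Mann-Whitney U tests with compact letter
    displays and PCA on the Fourier coefficient table. A synthetic seed
    generator provides populations of known morphotype for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
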