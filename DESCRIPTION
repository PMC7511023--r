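Package: lungmorph
Title: Semi-Automated Stereological Alveolar Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated stereological morphometry of lung parenchyma on
    raster fields of H&E-stained sections. Segments fields into binary
    tissue/air masks (thresholding, size-bounded exudate filtering, mask
    cleaning), overlays a quadratic test system of 64 points and 8+8 test
    lines, and counts reference points, septal points and air-tissue
    intersections to estimate septal volume density (VVsep), mean linear
    intercept (Lm), mean transsectional wall length (Lmw) and airspace
    surface density (SVair). Includes generators for synthetic ground-truth
    validation images (geometric "wallpaper" figures with exact area and
    perimeter, and histology-like phantoms), batch processing with QC
    overlays, and method-agreement statistics (regression against identity,
    Bland-Altman on relative differences, two-way random-effects ICC for
    absolute agreement, Welch's t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
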