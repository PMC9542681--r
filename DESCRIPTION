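Package: floralsym
Title: Directional Asymmetry Analysis for Flowers with Complex Symmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric-morphometric analysis of directional asymmetry in
    flowers whose organs are repeated in several orientations, such as the
    falls, standards and style branches of Iris. Provides generalized
    Procrustes superimposition, decomposition of shape variation into
    symmetric and asymmetric components under bilateral object symmetry,
    canonical variate analysis of orientation groups with permutation tests
    (Goodall's F and Pillai's trace), one-way ANOVA of centroid size,
    thin-plate-spline visualization of mean-shape differences, TPS landmark
    file input/output, and a synthetic flower-data generator with known,
    layered asymmetry structure for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
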