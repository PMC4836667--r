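Package: hypoxiafeat
Title: Quantitative Image Features of Chronic Tumor Hypoxia in Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts quantitative features of chronic (diffusion-limited)
    tumor hypoxia from anti-pimonidazole histology images: multithreshold
    tissue segmentation into hypoxic/viable/necrotic classes, radial
    intensity-gradient profiling around vessel-centroid landmarks with
    optimal segmented least-squares fits, quad-tree multiscale variance
    statistics, and Euler-Poincare characteristic signature curves. On top
    of the features it provides a viable/hypoxic/necrotic tissue
    transformation grammar, a spatially extended bounded linear temporal
    logic with a ready-made hypoxia proposition, a robust linear-regression
    similarity estimator with James-Stein coefficient shrinkage, and a
    seeded synthetic-lesion generator so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
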