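Package: wormlf
Title: Quantitative Light Field Microscopy for 3D Worm Behavioural Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional posture and locomotion of
    Caenorhabditis elegans from raw light field micrographs. A tiled
    microlens mosaic is rectified into a 4D light field, per-pixel depth is
    recovered by fusing defocus and correspondence cues over a refocusing
    sweep with a Markov random field, and 3D midline skeletons are extracted
    by segmentation, temporal Kalman filtering and spline fitting. Downstream
    analyses include posture and locomotion metrics (centroid speed,
    non-planar deviation, curving rate, directional autocorrelation), 3D
    eigenworm postural modes, and a rhodonea-curve model of body rolling
    during swimming. A synthetic phantom module generates ground-truthed worm
    locomotion, rendered scenes and raw mosaics consistent with the
    shear-refocus model, so the whole pipeline is testable without a
    microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
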