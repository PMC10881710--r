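Package: mvphantom
Title: Synthetic Mitral Valve MR Image Phantom and Sampling-Strategy
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Numerical phantom for cardiac magnetic resonance imaging of the
    mitral valve.  Generates a parametric labelled thorax/heart anatomy with a
    saddle-shaped bileaflet valve, simulates valve closure with position-based
    dynamics, synthesises multi-slice short-axis and radial long-axis image
    stacks (tissue intensity model, Gaussian noise, slab averaging,
    acquisition/reconstruction resampling), emulates expert point and spline
    annotations, and quantifies annulus and orifice geometry (diameters,
    height, projected areas), annotation bias, contour distances and
    point-to-surface distances so that image sampling strategies can be
    compared against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
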