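Package: fovdisp
Title: Foveated Log-Polar Model of Binocular Disparity Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com", role = c("aut", "cre"))
Description: An image-computable model of binocular disparity processing
    across a foveated visual field. Stereo image pairs are resampled through
    a discrete log-polar retino-cortical mapping with overlapping Gaussian
    receptive fields, processed by a population of phase-shift binocular
    energy units (V1) with divisive normalization, pooled into MT-like
    units tuned to vector disparity, and linearly decoded into cortical and
    retinal disparity fields. The package also provides the pink-noise
    disparity-corrugation stimulus generator, an adaptive-staircase
    psychophysics harness that runs the model as a simulated observer,
    log-parabola disparity-sensitivity-function fitting, and
    maximum-likelihood combination of sensitivity across annular regions of
    the visual field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png
Config/testthat/edition: 3
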