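Package: mrisr
Title: Super-Resolution Reconstruction of MRI-Like Images with a Small
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-image super-resolution for grayscale, MRI-like images
    using a three-stage convolutional network (feature extraction,
    nonlinear mapping, reconstruction) implemented from first principles:
    forward convolution, analytic backpropagation, selectable training
    losses (mean square error, cross-entropy, log-likelihood) and
    optimizers (gradient descent, momentum, RMSProp, Adam with bias
    correction). Includes a seeded phantom generator producing piecewise
    smooth knee-MRI-like test images with Gaussian or Rician noise, a
    configurable blur/decimate/spline-reupsample degradation model, PSNR
    and structural-similarity (SSIM) quality metrics with
    luminance/contrast/structure decomposition, a cubic-spline
    interpolation baseline, an end-to-end training and comparison
    harness, and chi-square homogeneity tests plus percentage summaries
    for small clinical contingency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
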