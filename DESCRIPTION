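Package: metaloa
Title: Meta-Learned Convergent Optimization for Compressed-Sensing MRI
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of undersampled magnetic resonance images by a
    learnable optimization algorithm (LOA) with a provable convergence
    safeguard. The variational objective combines k-space data fidelity with
    a learned nonconvex regularizer: a smoothed l2,1 norm of features from a
    complex-convolution extractor, weighted per acquisition task by the
    sigmoid of a task-specific scalar. The algorithm is unrolled phase by
    phase into a reconstruction network whose task-invariant parameters
    (filters, step sizes, smoothing level) and task-specific weights are
    trained jointly by a penalty-based bilevel scheme on cross-task
    mini-batches, with stair training over phases and fast adaptation of the
    task weight to unseen sampling patterns. Includes seeded generators for
    piecewise-smooth complex phantoms and radial, Cartesian, and
    variable-density Poisson undersampling masks, plus PSNR, SSIM, and NMSE
    image-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
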