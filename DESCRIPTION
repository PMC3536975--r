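Package: covisaBCI
Title: Closed-Loop Real-Time fMRI Brain-Computer Interface Based on
    Covert Visuospatial Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and decodes closed-loop real-time fMRI
    brain-computer interface sessions in which covert visuospatial
    attention (right/left/up/center) steers a telepresence robot. The
    package provides a synthetic 4D BOLD session generator with ground
    truth, rigid-body motion correction by stochastic gradient descent
    on a smoothed sum-of-squared-differences metric with cubic B-spline
    resampling, incrementally updated general linear model t maps with
    one-versus-rest contrasts, rank-based voxel selection with
    cluster-size filtering, smoothness-priors detrending with
    z-normalization, a one-against-one linear support vector machine
    decoder with tie-to-center voting, and a refractory control state
    machine driving a simulated robot through a target course.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    igraph,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
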