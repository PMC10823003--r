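Package: spdconn
Title: Functional Connectivity Networks on the SPD Manifold for EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds brain functional-connectivity graphs from multichannel
    EEG (phase locking value, Pearson correlation, spectral coherence,
    mutual information), converts them to symmetric positive definite
    matrices through thresholded graph Laplacians with eigenvalue
    rectification, and classifies them with a Riemannian SPD matrix
    network (BiMap/ReEig/LogEig layers with a dense softmax head,
    trained by orthogonality-constrained stochastic gradient descent).
    Includes decision-level fusion across connectivity features, a
    synthetic EEG generator with planted class-conditional coupling for
    end-to-end validation, and affine-invariant Riemannian geometry
    primitives for SPD matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang,
    yaml,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
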