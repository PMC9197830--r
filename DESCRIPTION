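Package: cvepriem
Title: Riemannian Transfer Learning for Code-Modulated VEP Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding of code-modulated visual evoked potential (c-VEP)
    brain-computer interfaces on the manifold of symmetric positive
    definite matrices. Implements super-trial covariance features with
    shrinkage estimation, affine-invariant and log-Euclidean distances
    and means, log-Euclidean data alignment (LEDA) for cross-subject
    covariance shift, training-accuracy-based source-subject selection
    (TSS), and minimum-distance-to-mean classification, together with an
    m-sequence codebook generator, a multi-subject synthetic c-VEP
    simulator, and a leave-one-subject-out evaluation harness comparing
    subject-specific and transfer-learning pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
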