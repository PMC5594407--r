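Package: bayestract
Title: Bayesian Active-Contour Tractography with Elastic Shape Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global tractography for 2D diffusion-tensor and HARDI
    (orientation distribution function) fields. Fiber curves between two
    endpoints are evolved by gradient descent on a posterior energy that
    combines a scale-invariant diffusion data term, an elastic shape prior
    learned from training fibers (square-root velocity representation,
    Karcher mean, tangent principal component analysis, truncated
    wrapped-normal density), and a length penalty. Includes a FACT-style
    deterministic streamline baseline, synthetic phantom generators
    (crossing, kissing, noisy-patch and arc-bundle scenes rasterized to
    smoothed tensor or ODF grids), and bundle-to-truth distance evaluation
    harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, jsonlite, RNifti, yaml, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
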