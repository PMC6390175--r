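Package: facersa
Title: Representational Similarity Analysis of Dynamic Face Form and Motion
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A sensor-level representational similarity analysis (RSA)
    pipeline for dynamic face stimuli. Computes configural-form and
    motion-pattern physical similarity measures from landmark-annotated
    videos (pairwise landmark distances; rigid head-motion correction via
    fiducial-triangle affine registration; feature-averaged landmark flow),
    builds categorical, perceptual-judgment and multichannel response-pattern
    similarity matrices, and runs the full RSA inference chain: Spearman and
    partial Spearman correlation over matrix cells, Fisher r-to-z, zero-phase
    Butterworth or Gaussian smoothing, group-level one-sample t-maps, and
    threshold-free cluster enhancement (TFCE) with sign-flip permutation
    correction. Includes synthetic generators for landmark videos, similarity
    judgments and multichannel epochs with planted representational
    structure, so every stage is testable end to end without real
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
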