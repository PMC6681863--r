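Package: meibographr
Title: Automated Morphometric Analysis of Infrared Meibography Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated analysis of infrared meibography images of the
    everted upper eyelid. Detects the tarsal-conjunctiva region of interest
    by fitting the upper (quadratic) and lower (constrained Chebyshev)
    eyelid boundaries followed by Chan-Vese active-contour refinement,
    segments and labels individual meibomian glands with band-pass
    filtering and adaptive thresholding, fragments fork-like compound
    glands, estimates the gland dropout-area percentage, computes per-gland
    morphometrics (length, width, relative length) and a polar-profile
    irregularity score against a reference envelope, and grades eyelids on
    the legacy Meiboscore scale and an objective scale derived by
    multi-level Otsu clustering. Includes a synthetic meibography generator
    with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    png,
    yaml,
    jsonlite,
    pracma,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
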