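Package: hoseg
Title: Automatic Seed Selection and Segmentation of Ultrasound Nodules via
    Higher-Order-Spectra Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic seed-point selection and seeded region-growing
    segmentation of hypoechoic nodules in B-mode ultrasound images.
    Implements neutrosophic S-function contrast enhancement with unsharp
    sharpening, speckle-reducing anisotropic diffusion (SRAD), block-wise
    Radon-transform bispectral-entropy features with a structural-similarity
    tiebreak for seed selection, constant-threshold seeded region growing,
    area- and boundary-based evaluation metrics, and a synthetic speckled
    lesion-phantom generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    stats,
    tools
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
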