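Package: speckinj
Title: Skinning-Injury Recognition from Biospeckle and Visible Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for recognising superficial skinning injury on potato
    tubers from two complementary CCD imaging channels. The biospeckle
    channel quantifies tissue activity from temporal stacks of laser
    speckle frames via the time history of the speckle pattern (THSP),
    its intensity co-occurrence matrix and the inertia moment statistic,
    including prefix-window time-span analysis. The visible channel
    extracts colour statistics and GLCM, Gabor and dual-tree complex
    wavelet texture features from region-of-interest patches. Two small
    classifiers - a least-squares support vector machine solved as its
    defining KKT linear system and binary logistic regression fitted by
    iteratively reweighted least squares - discriminate sound from
    injured skin under a stratified repeated 2:1 split protocol.
    Synthetic generators for dynamic speckle stacks with tunable
    temporal decorrelation and for two-class RGB skin patches with
    controllable grey-level contrast make the whole pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
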