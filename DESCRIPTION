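Package: seedhsi
Title: Hyperspectral Seed Image Processing and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch processing of line-scan hyperspectral images of seed trays:
    reading and writing ENVI header/raw cube pairs, white/dark reflectance
    calibration, noisy-band trimming, per-seed segmentation (intensity
    thresholding, connected components, hole filling, and decomposition of
    touching seeds into ellipses by Gaussian-mixture model selection), and
    export of per-seed hypercubes and mean reflectance spectra. Includes a
    synthetic scene generator with planted ground truth, seed- and pixel-level
    support vector machine classifiers, a compact 3D convolutional network for
    spectral-spatial patch classification with majority voting to seed calls,
    and wavelength importance ranking by split counts of a leaf-wise
    gradient-boosted tree ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
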