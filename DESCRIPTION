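Package: thrombotrack
Title: Quantification of Thrombus Deformation During Stent-Retriever Thrombectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic spatio-temporal segmentation and quantitative shape
    analysis of the thrombus in fluoroscopic x-ray frame series acquired during
    in-vitro stent-retriever thrombectomy. Frames are cropped to an operator
    region of interest, normalized against the temporal median baseline, and
    segmented by drag-seeded threshold flood fill propagated through time.
    Per-retrieval metrics include the pixel-count deformation index D, the mean
    contour-change distance CC, distal migration categories, shortening and
    elongation, stent grip and retrieval kinematics. Also provides colored
    temporal overlay rendering, mask-agreement reliability metrics (Dice,
    Jaccard, HD95, average surface distance), the study's nonparametric
    statistics (rank-sum tests with Cliff's delta, exact contingency tests,
    exact binomial intervals, Benjamini-Hochberg adjustment, covariate
    regression), and a calibrated synthetic phantom generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    oro.nifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
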