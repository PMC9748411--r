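Package: turtleBIS
Title: Calibration of Bioelectrical Impedance Spectroscopy Against
    CT-Derived Adipose Tissue in Sea Turtles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating bioelectrical impedance spectroscopy (BIS)
    as a field method for adipose tissue quantification in sea turtles, using
    computed tomography (CT) as the reference method. Provides a synthetic
    cohort generator with Cole-model-consistent impedance spectra, voxel CT
    phantoms with ground-truth adipose and false-positive masks,
    Hounsfield-unit threshold segmentation with false-positive removal and
    volume/mass accounting, impedance-index regression calibration with
    AICc-based model selection and split validation, and a method-agreement
    suite: Bland-Altman limits of agreement with confidence intervals,
    maximum allowed difference by inversion of the Lu et al. (2016) agreement
    power formula, Passing-Bablok regression, Lin's concordance correlation,
    and absolute percentage error summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
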