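Package: pupilrapd
Title: Quantification of Relative Afferent Pupillary Defect from Binocular Pupillometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for automated swinging-flashlight testing
    with a binocular pupillometer. Encodes the stimulation timeline, cleans raw
    90 Hz pupil-diameter traces (diameter cutoffs, shape-preserving PCHIP gap
    interpolation, running-mean smoothing, quality gating), extracts direct and
    consensual light-reflex constriction amplitudes, screens for efferent
    pathway defects, and scores the relative afferent pupillary defect (RAPD)
    as the one-tailed ratio of the stronger to the weaker eye's direct reflex.
    Includes ROC-based diagnostic-accuracy evaluation (AUROC, Youden cutoff,
    sensitivity, specificity, accuracy, precision, Matthews correlation
    coefficient) with severity stratification and low-score reallocation
    re-analyses, and a physiologically structured simulator of binocular pupil
    traces (reflex kinetics, afferent/efferent gains, hippus, blinks, sensor
    noise) for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
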