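Package: svcaPET
Title: Supervised-Clustering Pseudoreference Quantification for Dynamic TSPO PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying dynamic TSPO PET brain images without
    arterial blood sampling. Implements the two-stage supervised clustering
    algorithm (SVCA): kinetic-class library construction from framewise
    normalized scans of a training cohort, and voxelwise non-negative
    least-squares classification with gray-matter-ratio thresholding to
    extract a pseudoreference region. Quantification uses Logan graphical
    analysis (plasma-input total distribution volume with fractional blood
    volume correction) and the reference Logan model for distribution volume
    ratios (DVR), including DVR parametric maps. A synthetic-data module
    simulates multi-subject dynamic PET cohorts from compartmental kinetics
    with known ground truth, and a reliability module provides the standard
    test-retest battery: TRV/aTRV, the repeatability coefficient,
    ICC(A,1), Bland-Altman analysis, and group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    RNifti,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
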