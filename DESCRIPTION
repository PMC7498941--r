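Package: netthin
Title: Network Connectivity, Amyloid Burden and Longitudinal Cortical Thinning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable implementation of a preclinical Alzheimer's
    disease neuroimaging analysis chain: template-based rotation (TBR) extraction
    of resting-state network time courses from 4D BOLD data, aCompCor-style
    nuisance construction and removal (tissue-class temporal PCA, motion
    expansions, 90% variance PCA reduction), whole-network connectivity measures
    with between-subject adjustment, network cortical-thickness composites built
    from label volumes and surface vertices, amyloid-PET DVR/SUVR quantification
    with a Gaussian-mixture positivity cutoff, and linear mixed-effects models of
    how baseline default-mode connectivity and amyloid burden jointly predict
    longitudinal cortical thinning. A synthetic-data module generates every input
    with known ground truth so that the full pipeline can be exercised and its
    parameter recovery quantified.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    signal,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    mclust,
    pracma,
    MASS
Config/testthat/edition: 3
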