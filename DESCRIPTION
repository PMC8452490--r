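Package: meaphenotype
Title: Multiwell Micro-Electrode Array Neuronal Network Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of multiwell micro-electrode array (MEA)
    recordings from cultured neuronal networks: spike detection from raw
    extracellular traces, single-channel burst and network-burst detection,
    cross-correlation functional connectivity, extraction of 17 per-well
    activity and connectivity parameters, recommendation-based quality
    control, developmental-window pooling, and cohort statistics (parameter
    variability, PCA, batch variance decomposition, group comparisons, and
    power analysis).  Includes a ground-truth multiwell spike-train simulator
    with control-like and disease-like network phenotypes for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    nortest,
    jsonlite
Config/testthat/edition: 3
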