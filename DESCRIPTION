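Package: mxad
Title: Multiplex Gray-Matter and Amyloid Brain Connectome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Group-level multiplex (two-layer) brain network analysis for
    Alzheimer's disease research. Builds structural-covariance layers from
    subject-by-region gray matter (cortical thickness, subcortical volume)
    and amyloid-PET SUVR tables via covariate-adjusted partial correlation,
    computes nodal multiplex measures (overlapping strength, degree overlap,
    participation and clustering coefficients), detects multilayer
    communities by generalized Louvain optimization of two-layer modularity
    with persistence and variation-of-information model selection, and
    compares groups with density-averaged permutation tests under FDR
    control. Includes a synthetic cohort generator with planted covariance
    structure so the full pipeline is testable without controlled-access
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
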