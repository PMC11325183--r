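Package: conftree
Title: Adaptive Density-Clustering Trees for Molecular Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarises molecular conformational ensembles as hierarchical
    trees of density-connected clusters. Trajectory frames are superposed,
    reduced by principal component analysis, and clustered with DBSCAN at an
    adaptively increasing neighbourhood radius; clusters found at small radii
    (deep energy wells) nest inside progressively more diffuse clusters until
    all frames merge into a single root. Per-frame metadata (simulation
    source, categorical labels, numeric covariates) is projected onto tree
    nodes as counts and logarithmic colour intensities, representative
    conformations are extracted per node, and representatives are compared by
    RMSD after optimal superposition. A synthetic multi-well landscape
    generator provides ensembles with known well hierarchy for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
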