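Package: ionclust
Title: Ionic Cluster Detection and Population Dynamics from Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transient (pre-nucleation) ionic clusters in molecular
    dynamics trajectories of electrolyte and diastereomeric salt solutions
    using an ellipsoidal-shell neighbour criterion: a best-fitting ellipsoid
    is grown around each reference ion in concentric shells and ions are
    accepted into the cluster when their minimum interatomic distance to the
    accumulated cluster falls below a contact threshold. Per-frame cluster
    partitions are converted into normalized cluster-size state vectors,
    time-averaged size distributions with conservative block maximum-error
    bars, between-system population differences, and a principal component
    analysis of the population fluctuations that identifies the dominant
    association/dissociation modes. Includes readers for GRO, PDB and an
    extended-XYZ dialect, a synthetic planted-cluster generator for
    validation, and a command-line pipeline.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
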