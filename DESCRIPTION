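Package: fragreduce
Title: Virtual Reduction Planning for Fractured Bone Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, scriptable toolkit for planning the rigid reassembly
    (reduction) of fractured bone from CT-like label volumes. Implements the
    pre-processing used in haptics-assisted cranio-maxillofacial planning
    (bone thresholding, small-component removal, connected-component
    labeling), per-fragment precomputation of signed distance fields and
    surface point shells with outward normals, six degree-of-freedom
    penalty contact between rigid fragments, a static virtual coupling
    (translational plus rotational spring) stepped quasi-statically along
    scripted handle trajectories, fracture-surface painting with
    normal-colinearity-weighted snap-to-fit attraction forces, fragment
    grouping, plan import/export, and a synthetic fractured-phantom
    generator with ground-truth displacement transforms for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
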