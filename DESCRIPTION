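Package: mastoidplan
Title: Automated Volumetric Milling-Area Planning for Lateral Skull-Base Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans the bone volume to mill in mastoidectomy-style approaches to
    deep lateral skull-base targets (e.g. acoustic neuroma). Given voxelized
    critical-structure masks, a surgical target and a cylindrical tool model,
    the package generates the maximum feasible milling volume as a union of
    safe tool trajectories, reduces the target to an ordered effective
    boundary, parameterizes the volume with periodic polar control functions
    on a control plane, and optimizes the plan with the NSGA-III evolutionary
    algorithm under three objectives: constructability (spatial compactness
    and spectral-arc-length boundary smoothness), target accessibility, and
    injury to penalized structures. A deterministic synthetic temporal-bone
    phantom generator with closed-form geometry supports fully offline
    testing. Compute-heavy voxel kernels (signed distance fields, segment
    distance queries, cylinder rasterization, flood fill) are implemented in
    C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
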