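Package: ductr
Title: Morphometry of Paired Tubular Networks from Resin-Cast MicroCT Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the 3D architecture of two co-registered lumenized
    systems (e.g. intrahepatic bile duct and portal vein, or airway and
    pulmonary artery) segmented from micro-CT scans of double resin casts.
    Reads binary voxel masks (TIFF stacks, NRRD, NIfTI-1), reduces each mask
    to a one-voxel-wide medial-axis skeleton by homotopic thinning, converts
    the skeleton to a node/link network graph, and computes a morphometric
    panel: system volume, curved and chord lengths, percent tortuosity,
    main-branch diameter profiles, branch generations with side-branch
    handling, furcation census, three-region (hilar/intermediate/peripheral)
    subdivision, inter-system branch-point distances and surface-gap
    distances with cumulative distribution curves. A synthetic phantom
    generator produces ground-truthed single and dual tubular trees for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    RNifti,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
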