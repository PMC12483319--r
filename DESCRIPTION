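Package: synrec
Title: Segmentation and Morphometric Analysis of Synaptic Ultrastructure in Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing presynaptic ultrastructure from electron
    tomograms and micrographs: reading and writing volumetric data (MRC2014,
    HDF5, TIFF) with voxel-size metadata, generation of phantom tomograms with
    ground-truth labels for method validation, 2D/3D UNet semantic networks
    predicting foreground and boundary probabilities, structure-specific
    instance postprocessing (distance-seeded watershed for vesicles and
    mitochondria, size-filtered thresholding for active zones, per-slice
    watershed with multicut-style merging for synaptic compartments,
    vesicle-context filtering for ribbon structures), unsupervised mean-teacher
    domain adaptation to new imaging conditions, synapse morphometry (surface
    distances, inscribed-sphere diameters, vesicle pool assignment, mesh
    surface areas, area-normalised binned vesicle counts), and instance
    segmentation metrics (detection F1 at an IoU threshold, Dice, best dice,
    surface dice).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Rcpp,
    tiff,
    rhdf5,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
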