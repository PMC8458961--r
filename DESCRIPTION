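Package: neurocam
Title: CNN Classification of Brain Contrast Maps with Grad-CAM Visual Explanations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for group classification of task-fMRI contrast volumes and
    for visual explanation of the trained classifiers. Provides a synthetic
    phantom generator (brain mask, contiguous parcellation, group-dependent
    activation effects, cohort demographics), NIfTI volume handling with
    slice-as-channel packing and volumetric data augmentation, a compact
    convolutional neural network engine (modified LeNet-5 in 2D and 3D,
    trained with Adam), a grammar-based genetic-programming search over CNN
    architectures, a linear support-vector-machine voxel baseline, and
    from-scratch Grad-CAM, guided backpropagation and guided Grad-CAM saliency
    mapping aggregated into per-region cluster tables with peak coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
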