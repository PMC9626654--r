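Package: rflesion
Title: Morphometry and Volumetry of Radiofrequency Ablation Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying radiofrequency ablation lesions in
    myocardium from 3D imaging data. Generates synthetic lesion phantoms with
    exact ground truth, emulates thin-slice MRI-like and thick-slice gross
    pathology-like acquisitions, measures the four standard lesion dimensions
    (maximum depth, maximum width, depth at the maximum diameter, and estuary
    diameter) from binary lesion masks, estimates lesion volume by a closed
    formula, by Cavalieri slice summation ("point-by-point"), and by voxel
    counting, and compares measurement methods and observers with paired
    multilevel models suitable for repeated-measures method-agreement studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    lme4,
    RNifti,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
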