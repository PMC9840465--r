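Package: domescope
Title: Quantitative Imaging and Metabolic Assays for Renal Epithelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput image analysis for epithelial monolayer cultures:
    extended-depth-of-field fusion of z-stacks into all-in-focus composites and
    topography height-maps, phase-correlation stitching of tiled fields,
    segmentation and quantification of fluid domes (a readout of transepithelial
    solute transport), nuclei, mitochondrial morphology and autophagosome puncta.
    Includes a ground-truth synthetic scene generator for validation, plus the
    companion bench-assay computations: Mito Stress Test respiration parameters,
    ATP-per-protein, 2^-ddCt relative abundance, glutathione redox ratio,
    biopsy immunofluorescence Z-scores, and targeted metabolite quantification
    by ppm-window extracted-ion chromatograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    ranger,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
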