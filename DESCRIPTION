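Package: endoquant
Title: Quantitative Analysis of Endosomal Morphology, Tubule Networks and
    Organelle Codistribution in Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-quantification toolkit for starvation-induced endosomal
    tubulation studies: per-object morphometry (roundness from inscribed and
    enclosing circles, elongation from the second-moment ellipse), skeleton
    graph analysis of tubule networks (counts per area, lengths, triple
    connections), mask- and puncta-based codistribution statistics, paired
    along-tubule intensity enrichment at reference-channel extrema, and 3D
    shortest-distance codistribution classification under anisotropic voxel
    spacing. Includes a ground-truthed synthetic microscopy scene generator
    (vesicle fields, branched tubule networks with puncta, 3D ER-like
    meshworks with surface markers and endosomes) with a Poisson plus
    Gaussian camera noise model and Gaussian PSF blur, used to validate
    every statistic against planted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    tiff,
    yaml,
    withr,
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
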