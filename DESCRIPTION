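Package: retinovar
Title: Individual Variability Analysis for Retinotopic Maps of Early Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies inter-individual variability in polar angle and
    eccentricity maps of early visual cortex (V1-V3). Provides a circular
    difference metric for vertex-wise deviations from a group-average map,
    covariate constructions (curvature variability, normalized mean BOLD,
    split-half intra-individual variability), linear mixed-effects estimation
    of hemisphere/area/portion effects, weighted-Jaccard similarity with
    spectral clustering of discrete map motifs, and visual field sign analysis
    (mirror versus non-mirror representations) on gridded flat maps. Includes
    a synthetic flat-patch retinotopy generator with canonical, forked and
    truncated dorsal-V3 motifs so the full pipeline runs without any dataset
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    interp,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
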