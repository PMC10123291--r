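Package: gliamorph
Title: Microglial Morphometry, Cytokine Calibration and Composite Z Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro microglia immunophenotyping.
    Measures single-cell shape descriptors (circularity, roundness, aspect
    ratio, solidity, and a perimeter-to-area complexity index) from label
    rasters, classifies cells into round/amoeboid, polarized and ramified
    morphotypes, counts nuclei in a DAPI-like channel, calibrates multiplex
    immunoassay responses to concentrations with five-parameter logistic
    standard curves, normalizes measurements to untreated control wells,
    and summarizes genotype-by-treatment contrasts as pro- and
    anti-inflammatory composite Z scores with the matching nonparametric
    and parametric group statistics. A synthetic-data generator produces
    label images with ground-truth morphotypes and simulated multiplex
    plates so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
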