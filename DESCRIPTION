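Package: c4spectra
Title: C4 Photosynthetic Capacity from Gas Exchange and Canopy Hyperspectral Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates C4 photosynthetic capacity (maximal Rubisco carboxylation
    Vcmax, PEP carboxylation Vpmax, electron transport Jmax) and key leaf
    properties (specific leaf nitrogen, leaf mass per area) at field scale.
    Provides a forward C4 biochemical model with enzyme- and electron-transport
    limited regimes and bundle-sheath CO2 coupling, two-stage inversion of
    light (Ai) and CO2 (ACi) gas-exchange response curves, NDVI-masked plot
    reflectance and a vegetation-index library for canopy hyperspectral cubes,
    trait prediction by full-spectrum partial least squares regression with
    leave-one-out cross-validation and by PCA-guided stepwise index regression,
    genotype BLUPs and generalised heritability from row-column field trials,
    and a synthetic field-trial generator so the complete pipeline runs at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    MASS,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
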