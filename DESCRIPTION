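Package: platemix
Title: Spectral Unmixing of Fluorescence Plate-Reader Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts dual-emission fluorescence plate-reader time courses of
    fluorescent-protein-tagged microbial cultures into quantitative mean
    fluorescence-per-cell time series with propagated error bars. Measured
    fluorescence at two emission wavelengths is modelled as a linear mixture
    of reporter signal and cellular autofluorescence; the autofluorescence
    emission ratio is estimated from untagged (wild-type) wells as a smooth
    function of optical density using Gaussian-process regression with
    heteroscedastic noise. The package corrects for media background and for
    the nonlinear dependence of optical density on cell density, and
    propagates all calibration uncertainties into the final estimates by
    posterior sampling. A forward-model simulator of complete plate
    experiments with known ground truth supports validation without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
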