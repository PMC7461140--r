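Package: spectromed
Title: Mediation Analysis of Infrared Spectral Features for Tissue-Culture-Induced DNA Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links mid-infrared (ATR-FTIR) spectral band absorbances of plants
    regenerated through in vitro tissue culture to DNA sequence variation via
    methylation change, using regression-based mediation analysis. Provides
    spectral preprocessing (baseline correction, area normalization, band
    integration, windowed fragmentation, Gaussian peak deconvolution), simple
    mediation with percentile/bias-corrected bootstrap confidence intervals,
    Sobel/Goodman tests and variance accounted for, time-moderated mediation
    with conditional indirect effects and Johnson-Neyman regions of
    significance, a window-wise mediation screen over the fragmented spectrum,
    and seeded synthetic-data generators for spectra and mediation designs.
    Ships the 35-regenerant barley dataset the methods were developed on.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyselect,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
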