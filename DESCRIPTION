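Package: cropcast
Title: County- and Pixel-Level Crop Yield Prediction from Fused Vegetation
    Index Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs gap-free fine-resolution vegetation-index (VI) time
    series for a winter-wheat season (October to May) by fusing a sparse,
    cloud-gapped fine-grid sensor with a dense coarse-grid sensor (monthly
    maximum-value compositing, temporal interpolation, Savitzky-Golay
    smoothing, bilinear resampling and gap substitution), assembles monthly
    VI + climate feature matrices over a crop mask at county and pixel level,
    fits LSTM and gradient-boosted-tree yield regressors with ten-fold
    cross-validated hyperparameter selection, and evaluates them with a
    random 70/30 split, leave-one-year-out validation, relative-error
    banding, pixel-level yield mapping with county- and site-level
    validation, and a forward-month optimum-prediction-time analysis.
    Includes a fully deterministic synthetic-scene generator (seasonal VI
    phenology, correlated cloud gaps, coarse-sensor block aggregation,
    climate fields, county partitions and yields) so the whole pipeline is
    testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    xgboost,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
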