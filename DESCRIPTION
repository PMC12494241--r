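Package: geogain
Title: Kriged Treatment-Gain Mapping for Georeferenced Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps and quantifies yield-gain differences between two to five
    treatments in georeferenced strip trials. For each treatment the measured
    variable (e.g. yield in kg/ha) is interpolated over a regular grid by
    ordinary kriging from an 80% training split, corrected with a kriged
    residual (error) surface built from the 20% holdout, and clipped to the
    study area; gain surfaces are cellwise differences between the reference
    treatment's final surface and each other treatment's, summarised by
    min/max/sum/mean/std statistics and an HTML report. Includes empirical
    semivariogram estimation with weighted least-squares model fitting
    (linear, exponential, Gaussian, spherical), RMSE% and Pearson-r holdout
    validation, a Gaussian-random-field strip-trial simulator for testing,
    and GeoJSON/CSV/GeoTIFF input-output with UTM reprojection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    mgcv,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2,
    tiff
Config/testthat/edition: 3
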