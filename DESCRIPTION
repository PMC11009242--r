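Package: aquainterp
Title: Spatial Interpolation of Freshwater Calcium and pH Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning heterogeneous freshwater water-quality point
    records (dissolved calcium concentration and pH) into continental
    interpolated raster layers. Provides record quality control and
    harmonization (keyword exclusion, fraction selection, unit conversion,
    detection-limit handling, plausibility bounds), site-date median
    aggregation, projection to the North America Albers Equal-Area Conic
    system, empirical semivariogram estimation with Matern (Stein's
    parameterization) model fitting, nearest-neighbour, inverse-distance
    weighted and local ordinary-kriging prediction with kriging variance,
    leave-one-out and k-fold cross-validation with five error metrics
    (r, RMSE, MAE, MBE, median symmetric accuracy), inverse-distance
    parameter optimization, GeoTIFF raster export, and a synthetic data
    generator for end-to-end testing against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
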