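Package: cdlrefine
Title: Spatial-Temporal Decision-Tree Refinement of Categorical Land-Cover Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and corrects misclassified pixels in annual categorical
    land-cover rasters such as the USDA Cropland Data Layer. Each pixel is
    categorized against its 8-connected neighborhood (uniform, isolate,
    boundary, mix), compared with its dominating classification over a
    nine-year history (with stricter dominance thresholds for temporally
    constant features such as water, forest and developed land), and refined
    when the neighborhood majority and the historical dominant agree. A road
    post-processing step recovers linear developed features using an external
    reference mask, and the filter iterates until the raster stabilizes.
    Includes plain-text raster I/O (ESRI ASCII grid), a synthetic landscape
    generator with controlled noise injection for benchmarking, and
    evaluation utilities (refinement confusion matrices, county-level
    acreage tables, agreement statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
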