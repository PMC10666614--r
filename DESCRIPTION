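Package: sfer
Title: Overland Sewage Spill Footprints and Exposure Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the overland footprint of sanitary sewer overflows from a
    digital elevation model and a catalog of spill records, and quantifies the
    resulting exposure risk to people and land. Each spill is routed downslope
    with D8 single-flow-direction tracing to its first pooling cell; a
    volume-scaled accumulation zone is built around the start and end points
    from below-elevation terrain, and the traced flowpath is buffered into a
    worst-case corridor. Footprints are aggregated over census-tract and
    subwatershed polygons into population-risk and land-risk ratios, with
    quantile map classification, zonal overlays, and dual-metric site
    prioritization. Includes deterministic synthetic generators for terrain,
    spill catalogs, population grids and zone tilings, plus readers and
    writers for ESRI ASCII grids, GeoJSON layers and CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    deldir,
    generics,
    ggplot2,
    jsonlite,
    polyclip,
    purrr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
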