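Package: ptezone
Title: Pollution Indices, Seed Bioassays and Environmental Zoning for
    Mining-Impacted Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for risk-based environmental zoning of territories near
    gold-mining areas from soil-sample tables. Computes per-element Pollution
    Indices (PI) against geochemical background values, the Pollution Load
    Index (PLI, geometric mean of PIs), soil clean-up-standard exceedance
    screening, and a radish seed-germination phytotoxicity bioassay summarized
    by the Plant Vigor Index (PVI). Interpolates concentrations, PLI and PVI
    onto regular grids by inverse distance weighting with buffer clipping, and
    classifies territory into red/yellow/green management zones with area
    summaries. Includes a synthetic municipality generator (hot-spot structured
    concentrations with lognormal noise and a monotone dose-response bioassay)
    so the whole pipeline is testable end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
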