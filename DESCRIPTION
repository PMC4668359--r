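Package: mpagap
Title: Gap Analysis of Marine Protected Area Coverage of Species Ranges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for global marine protected-area (MPA) representation gap
    analysis on a half-degree geographic grid. Converts protected-area polygon
    tables into per-cell protected-fraction rasters under four subset
    definitions (any marine overlap, 'marine'-flagged, and their IUCN I-IV
    restrictions), thresholds species occurrence-probability maps into binary
    ranges, and computes per-species range coverage, representation bins,
    gap-species status, taxonomic summaries, probability-threshold sensitivity
    sweeps, gap-species density maps, and exclusive economic zone attribution.
    Includes a seeded synthetic-world generator (ocean mask, species
    probability maps with a preferred core and linear suitability decay,
    MPA polygons with coastal placement bias and incomplete IUCN attributes,
    EEZ polygons) with analytically known coverage for recovery testing, plus
    command-line entry points for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
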