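Package: burnzones
Title: Construction of Wildfire Burn-Zone Disaster Datasets from
    Multi-Source Incident Records
Version: 0.1.0
Authors@R:
    person("Burnzones", "Maintainers", email = "maintainers@burnzones.dev",
           role = c("aut", "cre"))
Description: Tools to build a national wildfire burn-zone disaster dataset
    from heterogeneous incident records and burn perimeters. The pipeline
    standardizes fire names, counties and dates across incident-report,
    state-annual-report and federal-assistance-declaration tables; links
    records for the same wildfire by fuzzy name matching (Jaro-Winkler),
    county overlap and ignition-date windows; resolves conflicts with
    source-precedence rules; applies harm criteria (civilian fatality,
    destroyed structure, federal fire-assistance declaration) with
    era-dependent fallbacks; attaches burn-zone geometry through tiered
    linkage to perimeter datasets with circular-buffer and point fallbacks;
    and classifies community proximity from smoothed gridded population
    density and wildland-urban-interface overlap. A seeded synthetic-data
    module emulates every source schema so the full pipeline is testable
    offline with known-truth inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
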