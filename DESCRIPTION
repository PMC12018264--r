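Package: cropSCS
Title: Safe Climatic Space Analysis for Food Crop Production Under Global Warming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates crop-specific Safe Climatic Spaces (SCS) -- empirical climatic
    niches in Holdridge life-zone parameter space (annual precipitation, biotemperature,
    potential evapotranspiration, aridity and an annual frost indicator) -- from gridded
    monthly climatologies and gridded crop production, projects them to global-warming
    levels across an ensemble of general circulation models, and quantifies climate risk
    to current production, changes in cropland area within each niche, and changes in
    potential crop diversity. Includes a deterministic synthetic-world generator with
    known ground-truth niches so the full pipeline is testable without external data,
    a 38-zone Holdridge life-zone classifier, warming-level interpolation between period
    climatologies, and ensemble majority-vote consensus machinery. Plain-text geospatial
    formats (ESRI ASCII grid, CSV, JSON) are used for all inputs and outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'binning.R'
    'climate.R'
    'scs.R'
    'projection.R'
    'diversity.R'
    'hlz-zones.R'
    'io.R'
    'risk.R'
    'synthetic.R'
    'pipeline.R'
    'tables.R'
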