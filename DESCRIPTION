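Package: ventrhythms
Title: Tidal Rhythm and Community Dynamics Analysis for Seafloor Observatory Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of tidal periodicity and spatial community structure in
    time series derived from deep-sea observatory video imagery. Implements the
    Whittaker-Robinson periodogram with NA-tolerant Buys-Ballot folding and
    permutation significance tests, Dixon-style nearest-neighbour segregation
    indices for labelled point patterns, permutation correlation tests with
    Holm correction at multiple sampling frequencies, and variation
    partitioning of multi-taxon density matrices between temporal eigenfunction
    (dbMEM) and environmental predictor sets. Includes a synthetic-data
    generator that emulates the sampling design of an hourly 23-day
    hydrothermal-vent recording (559 slots, missing frames, tidal forcing,
    autocorrelated noise, clustered point patterns) so the full pipeline is
    testable without any deposited data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
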