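Package: migrclass
Title: Classification of Migratory Strategies from GPS Telemetry
Version: 0.1.0
Authors@R: person("Movement Ecology", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies annual GPS movement trajectories of large herbivores
    into seven migratory strategies (dual-range migrant, multi-range migrant,
    commuter, poly-migrant, disperser, resident, gradual mover). Raw collar
    fixes are reduced to daily locations and converted to net squared
    displacement (NSD) series per migratory year (July 1 to June 30).
    Breakpoints in the mean NSD are found by exact dynamic-programming
    segmentation with a minimum segment length and BIC model selection;
    segments whose NSD distributions overlap are merged into common ranges via
    a kernel-density overlap coefficient; the surviving range shifts drive a
    decision tree over round trips away from the summer range. Includes
    migration timing and distance metrics, cohort summaries with year-to-year
    strategy switching, and a synthetic trajectory generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
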