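Package: landesca
Title: Cellular-Automaton Land-Use Scenarios and Perception-Based
    Ecosystem-Service Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates business-as-usual land-use/land-cover change on
    categorical rasters with a stochastic cellular automaton driven by
    stakeholder-elicited transition rules (source class, target class,
    conversion probability, Moore-neighborhood and zone conditions), and
    scores the resulting landscapes with a perception-based ecosystem-service
    assessment matrix on a common 0-100 scale.  Includes a seeded synthetic
    landscape generator calibrated to a coastal West African mosaic of
    settlement, rubber and oil-palm plantations, cropland, forest reserve,
    shrubland, waterbodies and mangrove wetland; Shannon-Wiener diversity
    scoring; area-change and ecosystem-service balance tables; trade-off
    classification; and spider-chart data export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
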