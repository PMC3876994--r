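Package: reefvalue
Title: Coral Cover Projection and Reef Ecosystem-Service Valuation Under
    Emissions Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Couples an episodic coral bleaching and ocean-acidification
    simulator with a benefit-transfer valuation of reef recreation and
    existence values. Emissions-scenario anchor tables are expanded into
    annual carbon dioxide, warming and aragonite-saturation series; per-cell
    coral cover is stepped monthly from 2000 to 2100 with up to six
    threshold-escalating bleaching mortality events; regional hardground-
    weighted cover declines are converted into discounted present values of
    recreational-use and existence value streams, and into the avoided loss
    attributable to mitigation. Includes a seeded synthetic-data generator
    for three United States reef regions (Hawaii, South Florida, Puerto
    Rico) so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    yaml
Config/testthat/edition: 3
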