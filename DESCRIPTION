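Package: marginalSOC
Title: Soil Organic Carbon Sequestration Scenarios on Marginal Land
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatially explicit exploration of soil organic carbon (SOC)
    sequestration on marginal land. Identifies SOC-deficient marginal target
    areas from gridded land-cover, soil and conservation layers; consolidates
    them into world-region by ecological-zone units; matches candidate plant
    species to those units by pedoclimatic tolerance; simulates long-horizon
    SOC dynamics with a five-pool monthly turnover model (RothC v26.3
    semantics, pedotransfer pool initialisation); subtracts water-erosion SOC
    losses via cover-management rescaling of mapped soil-loss rates; and
    reports net-SOC best-case area-by-species combinations. Ships a
    deterministic synthetic-world generator with machine-readable ground
    truth so the full pipeline is testable at toy grid scale.
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
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
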