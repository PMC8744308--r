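Package: fundedaccess
Title: Walkable Access to Contracted Health-Service Funding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures whether contracted health-service dollars are within
    walkable reach of high-hardship neighborhoods. Allocates contract amounts
    to service-delivery sites (headquarters and satellites), computes walking
    times over a street network, derives container and two-step floating
    catchment area (2SFCA) access measures in dollars per person, and
    cross-classifies census tracts by hardship tercile and funded-access
    tercile. Includes a synthetic-city generator that emulates the spatial
    structure such analyses assume (segregated hardship gradient,
    headquarters biased toward low-hardship areas, satellites toward
    medium and high-hardship areas) so the full pipeline is testable without
    restricted administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
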