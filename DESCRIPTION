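Package: duindex
Title: Data Usage Index Indicators for Biodiversity Dataset Usage Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Data Usage Index (DUI) family of indicators for
    primary biodiversity datasets from dataset inventories and portal
    usage-event logs: fourteen absolute and record-normalized indicators
    (searched/downloaded records and events, search and download density,
    usage and interest impact factors, usage ratio and balance, usage and
    interest scores), relative usage/interest impact indices against
    ratio-of-sums baselines, the species-profile-weighted Usage Crown
    Indicator, publisher size classes and the brute-force size adjustment,
    rank distributions with long-tail summaries, session reconstruction
    under the 30-minute inactivity rule with bounce filtering, and a seeded
    synthetic generator of inventories and event streams for testing
    indicator pipelines without access to a live data portal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
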