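Package: tokenward
Title: Token Economy-Based Hospital Bed Allocation Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-time, agent-based simulator of market-style hospital
    bed allocation. Wards broadcast token prices for their nursing service,
    an emulated physician agent assigns stochastic patient arrivals to the
    cheapest vacant ward with a random specialty premium, workload and token
    ledgers evolve under geometric lengths of stay, and the price-workload
    signaling relationship is quantified. Includes a command-based baseline
    allocator, full event-log replay, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
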