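Package: gonogo
Title: Simulation and Analysis of Automated Auditory Go/No-Go Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A discrete-event engine for home-cage auditory go/no-go
    (tone detection) operant conditioning: three-phase training protocols
    (waterspout habituation, behavioral shaping with progressive response
    delays, and an operant task with silent catch trials), multi-cage
    rotation scheduling, a parametric virtual-mouse agent that generates
    realistic lick streams with circadian structure and multi-day
    learning, a line-delimited JSON event-log format with trial-table
    extraction, and a behavioral-statistics suite (hit, false-alarm and
    early-response rates, signal-detection d-prime, first-lick latency
    distributions, lick-rate traces, and daily learning curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
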