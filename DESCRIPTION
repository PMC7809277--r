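Package: siem
Title: Social Influence and Event Model for Opinion Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of continuous opinion dynamics on random
    interaction networks under bounded confidence, individual certainty and
    stochastic external events. Individuals assimilate the opinions of
    like-minded network contacts when their certainty does not exceed that of
    the group, while time-bounded events of varying strength influence every
    eligible individual synchronously, sustaining opinion clustering and
    polarisation. Includes the population conflict statistic (standard
    deviation of opinions), reproducible parameter sweeps, a closed-form
    empirical relationship linking long-term conflict to homophily and event
    exposure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
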