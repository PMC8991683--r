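Package: epiforage
Title: Episodic-Control Foraging Simulations with Forgetting Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates reinforcement-learning agents that forage for reward in
    20x20 gridworld mazes using episodic control: a capacity-limited key-value
    memory of past state-action-return events, queried by Chebyshev
    nearest-neighbour retrieval over one of four state encodings (onehot,
    random, place-cell, successor representation) and pruned by an
    oldest-entry or random forgetting rule. Includes the full analysis layer:
    performance normalisation against the optimal average return, policy maps,
    preferred-direction and policy-entropy fields, retrieval match statistics,
    trajectory sampling from memory snapshots, per-state forgetting incidence,
    and Welch/Bonferroni comparisons across memory-capacity conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
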