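Package: groupswap
Title: Group-Formation Swap Games on Small-World Networks with Probability-Matching Agents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a round-based group-formation game in which coloured
    players on a periodic mesh with small-world links swap positions by
    sending and accepting requests, aiming to grow connected same-colour
    clusters. Implements the point-based and collective (average collective
    progress) payoff schemes, a probability-matching agent decision model
    (logistic utilities with an opt-out and a cluster-stability rule),
    behavioural metrics (activity, risk-averseness, strategy value,
    interaction matrices, point trajectories), maximum-likelihood fitting of
    the choice model from decision logs, and batch runners for all-human,
    hybrid, and all-agent team compositions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
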