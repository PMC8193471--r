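Package: ladmonitor
Title: Labor and Delivery Monitoring Algorithm with Expert-Panel Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A configurable rule engine for an abridged labor-and-delivery
    (LaD) monitoring algorithm that tracks six intrapartum parameters at
    evidence-based intervals, manages abnormalities by local-guideline rules,
    and enumerates the full factorized space of patient scenarios (1152 under
    the default configuration). Includes stratified scenario sampling for
    validation questionnaires, an inter-rater agreement framework (consensus
    action weights, directed pairwise sensitivity, false-positive rates,
    selection correlation, Spearman-Brown type reliability coefficient,
    confidence-interval based ranking), a seedable synthetic expert-panel
    simulator with controllable consensus, and reference fixtures from the
    original expert validation study for full reproduction of its results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
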