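Package: bsann
Title: Behavioral Sleep-State Annotation and Simulation for Infant Naps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epoch-based behavioral sleep staging for infants under one year.
    Extracts respiration, movement, eye and cry features per 30-second epoch
    from unobtrusive recordings, classifies each epoch into one of the five
    Prechtl behavioral states (quiet sleep, active sleep, quiet awake, active
    awake, vocalization) using the respiration-regularity criterion and
    movement heuristics, applies context rules (minimum state duration,
    sleep-onset exceptions, forbidden wake/quiet-sleep transitions), and
    quantifies agreement between annotation sources with Cohen's kappa,
    per-state kappa, and paired signed-rank tests. A built-in semi-Markov nap
    simulator generates ground-truth recordings with realistic 50-60 minute
    sleep cycles so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
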