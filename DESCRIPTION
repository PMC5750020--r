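Package: lingedge
Title: Evolutionary Distinctiveness and EDGE Prioritization for Language Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Conservation-prioritization toolkit for phylogenetic trees of
    languages (or species). Computes fair-proportion evolutionary
    distinctiveness (ED), endangerment-weighted EDGE scores from EGIDS-style
    vitality statuses, grafts taxa missing from a measured backbone tree into
    it using a hierarchical (Ethnologue-style) classification, and quantifies
    the robustness of ED rankings to incomplete tip sampling by randomized
    pruning experiments. Includes a synthetic-data generator so the full
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
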