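Package: querycase
Title: Rare-Disease Surveillance from Search-Query Logs and Registry Case Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for infodemiological surveillance of rare diseases from
    large-scale search-query logs compared against a national case registry.
    Matches queries against a disease keyword lexicon, converts query tallies
    into search popularity and search-estimated patient counts, ranks diseases
    annually in the search and registry systems, codes ranking differences into
    interval groups, quantifies inter-year stability of the two-system
    relationship with blocked Pearson consistency, adjacent-year intersections
    and a categorical-factor generalized linear model, and classifies diseases
    into two categories that guide epidemiological research strategy. A seeded
    synthetic-data module emulates the (inaccessible) query logs and registry
    and exposes noise-free expectations as a ground-truth oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
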