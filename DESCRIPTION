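Package: codhoming
Title: Genetic Assignment and Philopatry Testing for Tagged Atlantic Cod
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links microsatellite population structure, Bayesian genetic
    assignment of archival-tagged Atlantic cod, and behavioural
    classification of geolocation tracks, culminating in an unconditional
    exact (Boschloo) test for philopatric migration. Provides Genepop and
    CSV genotype input/output, Weir-Cockerham theta with permutation
    significance, per-allele Hardy-Weinberg screening, diversity
    statistics, classical multidimensional scaling of pairwise F_ST,
    leave-one-out self-assignment and Monte-Carlo exclusion tests against
    pooled spawning references, longitude-track validation and migratory
    behaviour classification, and a Balding-Nichols synthetic-data
    generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
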