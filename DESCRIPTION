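Package: clonesurvey
Title: Detection Power and Subclade Composition for rDNA Clone-Library Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing Sanger clone-library surveys of microbial
    symbionts, built around amphibian egg-capsule green algae. Implements the
    cumulative detection-probability model for rare non-target taxa
    (P = 1 - (1 - q)^n) and its inversions, masked uncorrected pairwise
    (p) distance analysis with per-group range tables, nearest-reference
    subclade classification with per-host composition accounting, a
    neighbor-joining tree stage with nonparametric bootstrap supports, and a
    synthetic clone-library survey generator so every stage is testable
    without sequence downloads. Results are returned as tibbles with
    broom-style tidy()/glance() methods and ggplot2 autoplot() figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
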