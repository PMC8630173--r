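Package: lbbbr
Title: Electrocardiographic Definitions of Left Bundle Branch Block
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring 12-lead electrocardiogram feature tables against
    published electrocardiographic definitions of left bundle branch block
    (ESC 2013, Strauss, AHA 2009 and its variants, and a proximal-block
    definition), reconstructing patient-level feature matrices consistent with
    published cohort-level counts, simulating synthetic LBBB cohorts with a
    latent proximal/distal class structure, and comparing definition
    concordance between cohorts with exact and asymptotic two-by-two tests.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
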