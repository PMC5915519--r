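Package: alphadose
Title: Preclinical Dosimetry and Efficacy Analysis for Targeted Alpha Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for preclinical targeted-alpha-therapy studies of
    At-211 radiopharmaceuticals such as 211At-MABG. Implements MIRD-style
    absorbed-dose estimation from organ biodistribution time-courses (%ID/g),
    tumor-growth and body-weight monitoring with endpoint rules and maximum
    tolerated dose determination, from-scratch Kaplan-Meier, log-rank and
    Dunnett-style many-to-one statistics, in-vitro assay normalisations, and
    seeded synthetic-data generators that emulate the statistical structure of
    such studies for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    multcomp,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
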