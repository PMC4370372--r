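Package: rundx
Title: Run Chart Rules and Their Diagnostic Value
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Run chart analysis for quality-measure time series: median-based
    runs, crossings, longest-run and longest-trend statistics; the Anhoej,
    Perla and Carey run chart rule sets with dynamic signal limits; and a
    Monte-Carlo framework that scores each rule set's sensitivity,
    specificity and positive/negative likelihood ratios for detecting a
    sustained shift in process mean. Includes a tidy simulation grid over
    baseline and post-baseline lengths, ggplot2 charts, and a small
    command-line front-end for analysing CSV series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
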