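Package: vlwburden
Title: Monetized Burden-of-Disease Valuation and Disparity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monetizes province-, sex- and age-disaggregated disease burden
    (DALYs and YLLs) into value-of-lost-welfare (VLW) estimates under
    alternative value-of-statistical-life benchmarks, including income-based
    benefit transfer of reference VSLs. Normalizes welfare losses by
    provincial GDP and quantifies gender disparity (male-female relative
    difference), geographic disparity (location quotients and a disparity
    index), and labels provinces by exact one-dimensional k-means
    clustering. Includes a synthetic burden/economy data generator that
    emulates GBD-style result exports, readers and writers for those
    tables, and an end-to-end pipeline with a reproducible run manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
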