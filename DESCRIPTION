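Package: alosbench
Title: Aggregated Length-of-Stay Benchmarking for Digestive Cancer Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds benchmark tables of hospital resource use after resection
    for cancers of the digestive system from patient-level admission records.
    Extracts an index-resection cohort with configurable procedure/diagnosis
    code maps, links index stays, same-date transfers of care and 30-day
    readmissions into an aggregated length of stay (a-LOS, the number of
    nights spent in any hospital within 30 days of surgery), and summarises
    index LOS, transfer and readmission rates and a-LOS by organ site and
    surgical access. Includes a calibrated synthetic patient-registry
    generator with ground truth so the full pipeline is testable without
    access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
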