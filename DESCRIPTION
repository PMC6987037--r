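Package: dropcount
Title: Method Comparison for Viable Probiotic Enumeration by Droplet
    Digital PCR, Plate Count and Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Tools for enumerating viable probiotic bacteria from droplet
    digital PCR (ddPCR) partition counts via the Poisson occupancy model,
    from serial-dilution plate counts via the countable-window rule, and
    from gated flow-cytometry events, together with the statistics used to
    compare enumeration methods: per-batch coefficients of variation,
    Pearson correlation, regression against the identity line, and
    Bland-Altman relative-difference agreement with 95% limits of
    agreement. Includes a measurement-process simulator that emulates a
    multi-strain production study (50 batches, six strains, method-specific
    replicate structure and noise) so the full analysis pipeline can be
    exercised and validated without access to proprietary batch records.
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
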