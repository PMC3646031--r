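Package: dormancy
Title: Stochastic Models of Breast Cancer Dormancy and Relapse
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form recurrence-free-interval (RFI) curves, hazard
    rates and conditioned micrometastasis moments for four continuous-time
    Markov models of post-resection breast cancer dormancy; an exact
    event-driven cohort simulator; Kaplan-Meier input/output with hazard
    estimation and extrapolation; Monte Carlo random-search fitting of
    models to digitized relapse curves; and diagnostics for hazard maxima,
    relapse-rate peaks and hidden micrometastasis burden.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
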