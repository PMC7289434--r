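Package: flowsel
Title: Congestion Feature Engineering and Selection for Healthcare Workflow Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting patient delay and wait times in outpatient
    imaging workflows from Hospital Information System style event logs.
    Provides a discrete-event simulator of scheduled, hybrid and walk-in
    facilities; an 84-feature operational catalog (congestion, customer,
    resource, task and time features) computed with leakage-safe as-of queue
    reconstruction; repeated forward-stepwise linear-regression and
    random-forest permutation-importance feature selection; and
    cross-facility / cross-model feature-transferability evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ranger,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
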