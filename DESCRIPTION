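Package: teledermacc
Title: Management-Plan and Diagnostic Accuracy of a Teledermatoscopy
    Service from Linked Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Retrospective evaluation of a store-and-forward
    teledermatoscopy service for melanoma detection by deterministic
    linkage of a service database (index tests) to a national
    histopathology registry extract (reference tests).  Implements the
    three-criterion record matcher with worst-case and best-case
    resolution of ambiguous linkages, index-test classification into
    positive, negative and inconclusive outcomes, exact Clopper-Pearson
    binomial confidence intervals, standard-logit intervals for
    predictive values, the Buderer sample-size formula, test-yield
    accounting, a STARD-style participant-flow summary, and a synthetic
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
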