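Package: semnetverify
Title: Sparse Semantic Network Simulation of Category Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates speeded category verification ("A carrot is a
    vegetable") with a sparse labeled semantic network model: a stochastic
    strength-ordered retrieval race over SUBSET/SUPERSET/COORD associations
    bounded by a stopping length, followed by production-rule evaluation of
    the retrieved label 2-tuple. A feature-comparison counter model with a
    criterion shift is included as the rival account and as the fallback
    strategy for cross-category false contexts. Ships a synthetic taxonomy
    and stimulus-list generator mirroring classic blocked false-context
    designs, an experiment harness with per-participant outlier trimming,
    and the matching inferential toolkit: paired t, Cohen's d,
    unit-information Bayes factors, noncentral-t power, contrast tables, and
    binned standardized-effect distribution comparison.
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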