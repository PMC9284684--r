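Package: tdncd
Title: Time-Distance Nodal Connectivity Diversity for Dynamic Functional
    Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies per-region reconfiguration of dynamic functional
    connectivity (dFC) in resting-state fMRI via the time-distance nodal
    connectivity diversity (tdNCD) statistic. Provides sliding-window
    correlation networks, the tdNCD profile per region, site-wise two-sample
    tests combined across acquisition sites with a weighted Liptak-Stouffer
    meta-analysis under Bonferroni correction, and a nested
    leave-one-site-out classification framework (a compact fully connected
    network plus SVM, KNN, logistic regression and LDA baselines) with
    t-test feature selection. A Markov state-switching Gaussian simulator
    generates multi-site cohorts with controllable ground-truth
    reconfiguration effects so the entire pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    e1071,
    caret,
    glmnet,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
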