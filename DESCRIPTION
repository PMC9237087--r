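Package: panelnet
Title: Panel Graphical Vector-Autoregression for Sessional Symptom Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates lag-1 panel graphical vector-autoregression (panel
    GVAR) models from multi-subject, multi-session symptom panels with
    missing data, using full-information maximum likelihood. Decomposes
    symptom covariation into a directed temporal network, an undirected
    contemporaneous network of innovation partial correlations, and an
    undirected between-person network of stable means. Provides SEM fit
    indices (chi-square, NFI, PNFI, TLI, RFI, IFI, CFI, RMSEA with
    noncentral confidence intervals), holdout and equality-constrained
    refits for generalizability testing, Expected Influence centrality,
    per-wave unregularised Gaussian graphical model selection by stepwise
    EBIC search over a graphical-lasso path, node-redundancy screening,
    and a synthetic-cohort generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
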