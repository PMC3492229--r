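Package: biopsyMDP
Title: Optimal Breast-Biopsy Threshold Policies via a Finite-Horizon Markov
    Decision Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential decision-analytic model of the annual choice between
    breast biopsy and continued annual mammography. A finite-horizon Markov
    decision process over integer breast-cancer risk scores (0-100) is solved
    by backward induction to maximize quality-adjusted life years, yielding an
    age-indexed optimal biopsy threshold. Includes empirical estimation of the
    annual risk-score transition kernel from longitudinal finding trajectories
    (with linear-interpolation annualization and single-observation exclusion),
    QALY reward construction from mortality and post-diagnosis survival tables
    with biopsy disutility and a treatment-effectiveness factor, one-way
    sensitivity analysis over the model's four headline parameters, and a
    synthetic-cohort generator emulating a screening mammography population so
    the full pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
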