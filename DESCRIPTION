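Package: facetCEA
Title: Cost-Utility Analysis of Lumbar Facet Arthroplasty Versus Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A decision-analytic cost-utility pipeline comparing a
    motion-preserving lumbar facet arthroplasty device (TOPS) against
    transforaminal lumbar interbody fusion (TLIF). Implements a five-state
    cohort Markov model over a variable-length cycle schedule with discounted
    cost and QALY accumulation from health-system and societal perspectives,
    VAS/ODI-based health-state construction and transition-matrix estimation,
    dual-payer costing with adverse-event and productivity-loss components,
    incremental cost-effectiveness metrics (ICER, net monetary benefit),
    scenario and one-way (tornado) sensitivity analyses, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, and a
    Gaussian-copula synthetic randomized-trial generator for end-to-end runs
    without patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
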