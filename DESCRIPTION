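Package: hpaxis
Title: Bistable Delay-Differential Modelling of the Hypothalamic-Pituitary-Adrenal Axis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a nondimensional delay-differential model of the
    hypothalamic-pituitary-adrenal (HPA) axis in which stored and circulating
    CRH, ACTH, pituitary glucocorticoid receptor and cortisol interact through
    delayed negative feedback. Provides a deterministic method-of-steps
    integrator, limit-cycle characterization of the pituitary-adrenal
    subsystem, construction of the c- and cs-nullclines by period averaging,
    detection and classification of bistable fixed points (normal versus
    low-cortisol "diseased" states), one-parameter nullcline sweeps, and
    in-silico pharmacological challenge protocols: the dexamethasone
    suppression test, phase-controlled ACTH (cosyntropin) stimulation, and a
    combined two-stage dexamethasone-plus-stressor test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
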