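Package: dualmem
Title: Dual-Memory Model Analysis of the Testing Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the dual-memory account of retrieval practice for
    cued recall: parameter-free predictions of test-condition performance
    from restudy performance (PC_T = 2*PC_R - PC_R^2), a one-parameter
    extension in which study and test memory strengths are correlated
    through a Gaussian copula, cumulative-distribution matching of observed
    against predicted proportion-correct distributions, estimation of the
    strength correlation rho by matching mean test performance, and the
    accompanying inference chain (mixed-design ANOVA, pairwise t tests,
    default JZS Bayes factors with Raftery evidence labels). A synthetic
    cohort generator reproduces the trial-level structure of a two-group
    (low/high semantic relatedness) restudy-versus-test-with-feedback
    design so the full analysis pipeline can be exercised and validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
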