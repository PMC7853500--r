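Package: tcdcm
Title: Thalamocortical Conductance Neural-Mass Modelling of Evoked
    Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and inverts a conductance-based thalamocortical
    neural-mass model of the visual cortical column for the analysis of
    laminar connectivity changes in evoked potentials, such as those
    induced by sensory long-term potentiation paradigms.  Provides the
    eight-population (six cortical, two thalamic) model with AMPA, NMDA
    (magnesium-gated), GABA-A, GABA-B, M- and H-channel conductances and
    thalamocortical conduction delays; condition-contrast general linear
    models over connection gains and receptor decay rates; variational
    Laplace (Gauss-Newton) inversion with a free-energy approximation to
    the log model evidence; fixed- and random-effects Bayesian model
    selection with protected exceedance probabilities and the Bayesian
    omnibus risk; repeated-measures MANOVA and FDR-corrected univariate
    follow-ups on condition-specific parameter estimates; and a seeded
    synthetic-cohort generator for end-to-end recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    readr,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
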