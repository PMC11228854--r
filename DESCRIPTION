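Package: epibalance
Title: Deterministic Mutation/Epimutation-Selection Balance with Inbreeding
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a deterministic diploid model of deleterious
    mutation/epimutation-selection balance at a single locus with three
    (epi)allelic states: a wild-type allele, a deleterious allele, and a
    deleterious epiallele of the wild-type.  The life cycle comprises
    mating under partial inbreeding, paramutation, selection, spontaneous
    epimutation, and mutation.  The package provides the exact
    single-generation recursion and its stage operators, iteration to
    equilibrium with damped-cycling diagnostics, first-order analytic
    equilibrium approximations with regime (validity) conditions,
    numerical local stability analysis via the Jacobian of the reduced
    two-dimensional map, parameter sweeps, bisection for bifurcation
    thresholds in the paramutation rate, a preset registry of published
    parameter sets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
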