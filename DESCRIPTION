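Package: dihi
Title: Disease-Induced Herd Immunity in Mean-Field Epidemic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Four mean-field epidemic models on structured populations
    (degree-based heterogeneous mean-field SIR, heterogeneous pairwise SIR
    with a clustered triple closure, an edge-based compartmental model with
    households of size four and community links, and an age-structured SEIRD
    model driven by age-banded mixing matrices), together with their basic
    reproduction number calculators, an exact-event Gillespie simulator on
    explicit household/configuration-model networks used as a validation
    oracle, and the machinery for one-shot lockdown experiments: trigger
    based interventions, optimal intervention-strength search, second-wave
    detection and disease-induced herd immunity (DIHI) levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
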