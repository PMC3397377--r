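Package: seqddm
Title: Sequential Effects and Post-Error Dynamics in an Adapted Drift
    Diffusion Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling sequential effects and post-error slowing in
    two-alternative forced-choice tasks with an adapted drift diffusion model
    (DDM). Provides closed-form first-passage statistics of the pure DDM
    (error rate, mean decision time, and conditional mean decision times for
    correct and error trials) together with an Euler-Maruyama Monte-Carlo
    oracle; trial-to-trial adaptation mechanisms (initial-condition priming
    from an exponentially decaying memory of repetitions, and post-error
    threshold modulation); transition-oriented Markov stimulus-sequence
    generators and synthetic-subject simulation; sequence-sorted behavioral
    analysis (RR/AR/RA/AA labelling, correct/error splits, pre/on/post-error
    reaction times, the sequential RT tradeoff, R-line/A-line geometry); and
    least-squares fitting of condition summary vectors with information
    criteria for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
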