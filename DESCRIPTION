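Package: ruleflex
Title: Stochastic Attractor Models of Cognitive Stability and Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling cue-based task switching and distractor
    inhibition with a reduced two-population attractor model of task-rule
    working memory coupled to a four-choice nonlinear drift-diffusion
    decision process. Simulates trial-level behaviour (choices and reaction
    times) for baseline, distractor and switch conditions, fits the model to
    behavioural logs by pseudo-marginal Metropolis-Hastings sampling of a
    composite multinomial/Kolmogorov-Smirnov posterior, reconstructs the
    rule module's potential landscape from the steady state of its
    Fokker-Planck equation, quantifies attractor stability as the minimal
    Hamilton-Jacobi path action between rule states, and predicts BOLD
    regressor timecourses from simulated population activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
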