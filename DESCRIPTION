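Package: ramplab
Title: Simulating Phasic, Tonic and Quasi-Tonic Dopamine Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded simulator suite for three computational accounts of
    ramp-like dopamine signals in the nucleus accumbens: temporal-difference
    prediction errors generated by resolution of uncertainty about action
    timing within an actor-critic semi-Markov decision process; dopaminergic
    gain control of a drift-diffusion decision process with Ornstein-Uhlenbeck
    tonic fluctuations and phasic transients; and a discounted-vigour model in
    which a quasi-tonic signal proportional to the discounted value function
    ramps towards goals. Includes a shared measurement model (alpha-function
    dopamine response kernel, asymmetric prediction-error scaling, causal
    convolution, event-aligned trial averaging), hazard-function timing
    machinery, average-reward relative-value solvers, softmax latency policies,
    optimal-latency analysis with an analytic cost bound, and a config-driven
    experiment runner that reproduces each simulation as CSV/JSON products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
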