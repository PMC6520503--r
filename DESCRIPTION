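Package: reachgain
Title: Value-Sensitive Rapid Visuomotor Response Gains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of rapid visuomotor feedback responses
    to cursor jumps in perturbed reaching, where the rewards and
    probabilities of potential targets are manipulated. Provides a
    synthetic-data generator emulating three block designs (reward,
    probability, and combined value manipulations), preprocessing of 1 kHz
    force/acceleration traces (zero-phase low-pass filtering, baseline
    subtraction, direction pooling, windowed response-gain extraction),
    ROC-area response-onset detection with dog-leg breakpoint fitting,
    hierarchical Bayesian fitting of probability, reward, risk-neutral and
    risk-sensitive relative-value models of response gains (via JAGS), and
    model comparison through WAIC, pairwise Bayes factors and Kass-Raftery
    evidence labels, plus a hit-rate versus gain regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    rjags,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
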