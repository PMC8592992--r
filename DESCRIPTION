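Package: volstoch
Title: Joint Estimation of Volatility and Stochasticity in Adaptive Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Kalman-filter learner whose two noise hyperparameters --
    volatility (process noise) and stochasticity (observation noise) -- are
    tracked online by a Rao-Blackwellized particle filter. Provides the
    generative model (multiplicative Beta dynamics on inverse noise, or
    Gaussian random walks in log space), the particle-filter learner with
    volatility- and stochasticity-lesioned variants, a battery of simulated
    conditioning and decision tasks (factorial noise designs, reward-rate
    switching, conditioned suppression, partial reinforcement, serial
    prediction, probabilistic reversal, change-point schedules), softmax
    choice coupling, behavioral summary statistics (win-stay/lose-shift,
    relative log learning rate), and an experiment runner with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
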