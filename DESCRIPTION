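Package: qcinfer
Title: Stochastic Quantal-Content Analysis and Presynaptic Parameter
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact transient and steady-state statistics of the quantal
    content (QC) of chemical synapses under a per-docking-site stochastic
    model with time-varying release, refilling and undocking
    probabilities.  Provides the occupancy recursion and its closed form,
    binomial QC distributions, steady-state Fano factor and lag
    autocorrelation, conversion between per-interval probabilities and
    continuous-time docking/undocking rates, seeded Monte-Carlo
    simulation of fixed-frequency and randomly timed action-potential
    trains, quantal-size noise for evoked amplitudes, and an inference
    toolkit: empirical fluctuation statistics with bootstrap confidence
    intervals, joint Fano-factor/correlation moment inversion with root
    disambiguation, least-squares transient fitting, the
    Elmqvist-Quastel pool estimator, time-varying refilling-schedule
    fitting (least squares and maximum likelihood), and feasible-region
    mapping of the (release, refilling) probability plane.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
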