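Package: sdmux
Title: Synchrony-Division Multiplexing Encoding Models for Neural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for synchrony-division
    multiplexing (SDM), a population coding scheme in which synchronous
    spikes of a homogeneous neural ensemble signal fast, abrupt stimulus
    features while asynchronous spikes carry the slowly varying stimulus
    intensity. Provides generators for mixed Ornstein-Uhlenbeck plus
    sparse-event current stimuli, a Morris-Lecar conductance-based
    ensemble simulator operating in the hybrid (integrator/coincidence
    detector) regime, kernel-smoothed population rates and
    synchrony-based spike classification, spike-triggered average and
    covariance estimators with information-theoretic subspace selection
    (iSTAC), per-stream linear-nonlinear (LNL) cascade fitting, a
    two-stream augmented LNL encoder, a one-stream Poisson GLM baseline,
    and linear stimulus reconstruction from classified spike trains.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
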