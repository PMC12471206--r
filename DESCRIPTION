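Package: rtebalance
Title: Bioenergetic Modelling of Retrotransposon Activity and Cellular ATP Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A kinetic simulator of the cellular energy balance in the presence
    of active retrotransposons (LINE-1 and Alu). Implements a 12-variable stiff
    ODE model coupling free ATP to transcription, translation, ribosome and
    reverse-transcriptase complex formation, genomic insertion of new
    retrotransposon copies and DNA replication costs. Provides trajectory
    simulation with the Radau method, steady-state location with linear
    stability analysis, parameter response coefficients and nonlinear scans,
    copy-number perturbation scenarios with ATP-drop metrics, an instantaneous
    ATP budget decomposition, and Levenberg-Marquardt calibration of the free
    rate constants against wild-type ATP and retrotransposon counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    jsonlite,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
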