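Package: serogen
Title: Individual-Based Simulation of Serological Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular, individual-based generative framework for serological
    data. User-composable exposure, immunity, antibody-kinetics and
    observation models produce latent immune histories, latent biomarker
    (antibody titer) trajectories, and observed assay measurements for a
    simulated population. Includes force-of-exposure driven Bernoulli
    exposure processes, boosting-waning antibody kinetics with random
    effects, assay sensitivity/specificity and limits of detection, a
    seropositivity-threshold evaluation utility, and a configuration-driven
    command-line shell for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
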