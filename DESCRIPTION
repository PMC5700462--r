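Package: hairpinkinetics
Title: Three-State Hybridization Kinetics of Hairpin-DNA Biosensor Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule conductance traces from
    hairpin-DNA-decorated nanowire field-effect biosensors. Provides a
    destination-resolved semi-Markov simulator for three-state (duplex, hairpin,
    single-stranded) hybridization dynamics, trace rendering with Gaussian and
    1/f noise, amplitude-histogram Gaussian-mixture model selection, hidden
    Markov model idealization of noisy traces into dwell sequences,
    direction-resolved dwell-time and lifetime estimation with
    transition-probability matrices, state-occupancy statistics,
    occupancy-profile SNP allele calling, and two-state sigmoid melting-curve
    (Tm) fitting. All results are returned as tibbles with tidy() and glance()
    methods and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    graphics,
    grDevices,
    tools,
    generics,
    jsonlite,
    mclust,
    minpack.lm,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
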