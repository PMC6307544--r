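Package: holosim
Title: Coevolution of Boolean Host and Microbial Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the coevolution of a host gene-regulatory network with its
    microbiota, both modeled as random Boolean (Kauffman) networks. Host networks
    evolve under mutation and elitist selection so that the summed activity of
    designated signal nodes matches predefined target time series (tasks), while
    faster-mutating microbial networks can establish cross-network regulatory
    interactions with the host. Provides the network dynamics and mutation
    operators, task and error functionals, the population-level evolutionary
    engine, and scenario runners for control versus holobiont evolution,
    multitask adaptation with specialized microbial niches, dysbiosis
    (disconnection) experiments and diversity-loss sweeps, together with tidy
    per-generation trajectory tables, ggplot2 visualizations and JSON/TSV
    serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
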