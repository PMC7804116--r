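Package: promotherm
Title: Thermodynamic Modelling and MPRA Analysis of Inducible Promoter Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing combinatorial libraries of IPTG-inducible
    bacterial promoters, processing massively parallel reporter assay (MPRA)
    barcode counts into per-variant expression and induction fold change, and
    fitting a statistical-mechanics model of promoter occupancy to the measured
    expression. The model enumerates RNA polymerase and LacI repressor occupancy
    states (including DNA-looped states), assigns Boltzmann weights from
    binding free energies in units of kT, and predicts expression in uninduced
    and IPTG-induced conditions. Binding energies are inferred by multistart
    bounded nonlinear least squares on log10 expression. A synthetic-data
    module simulates complete MPRA experiments (overdispersed barcode counts,
    replicate structure, scrambled-operator negative controls) so that the
    whole pipeline, including parameter recovery and zero-shot prediction of
    three-operator architectures, can be exercised without external data.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    lhs,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
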