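# Shared fixtures built in code.

# a reduced two-operator design: 4 operators x 2 x 2 cores x 4 operators,
# small enough that a noiseless fit runs in seconds
small_pcombo <- function() {
  enumerate_library("pcombo", assemble = FALSE) |>
    dplyr::filter(
      .data$proximal_op %in% c("O_1", "O_sym", "O_3", "O_scram"),
      .data$distal_op %in% c("O_1", "O_sym", "O_3", "O_scram"),
      .data$minus35 %in% c("TTGACA", "TCGACC"),
      .data$minus10 %in% c("TATAAT", "TATGTT")
    )
}

small_truth <- function(seed = 42) {
  sample_ground_truth(
    seed,
    operators = c("O_1", "O_sym", "O_3", "O_scram"),
    core_pairs = c(
      "TTGACA:TATAAT", "TTGACA:TATGTT", "TCGACC:TATAAT", "TCGACC:TATGTT"
    )
  )
}

# noiseless expression table straight from the model
noiseless_expression <- function(designs, params) {
  dplyr::bind_rows(
    predict_expression(designs, params, induced = FALSE),
    predict_expression(designs, params, induced = TRUE)
  )[, c("variant_id", "condition", "expression")]
}

# minimal hand-built barcode count table (one condition/replicate pair per
# call unless expanded)
toy_counts <- function() {
  tidyr::expand_grid(
    tibble::tibble(
      barcode = c("b1", "b2", "b3", "c1", "c2", "c3"),
      variant_id = c("v1", "v1", "v1", "v2", "v2", "v2")
    ),
    condition = c("uninduced", "induced"),
    replicate = 1:2,
    assay = c("DNA", "RNA")
  ) |>
    dplyr::mutate(count = 10L)
}
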