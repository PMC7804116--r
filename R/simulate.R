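# Synthetic MPRA experiments: ground-truth thermodynamic parameters, true
# per-variant expression from the occupancy model, and overdispersed barcode
# counts with the study's layout (2 conditions x 2 replicates x {DNA, RNA}).

#' Simulation configuration
#'
#' @param barcodes_per_variant Mean of the truncated-at-1 Poisson barcode
#'   count per variant (default 10; the assayed libraries averaged roughly
#'   7-70).
#' @param dna_depth,rna_depth Total reads per sample (default 1e6).
#' @param dispersion Negative-binomial size parameter of the count noise
#'   (default 10; larger = closer to Poisson).
#' @param replicate_noise_cv Coefficient of variation of the lognormal
#'   variant x replicate expression effect (default 0.1).
#' @param n_controls Number of dedicated scrambled-operator negative-control
#'   promoters added to the experiment (default 30).
#' @param n_replicates Biological replicates per condition (default 2).
#' @param fixed_barcodes If `TRUE`, every variant gets exactly
#'   `barcodes_per_variant` barcodes instead of a truncated-Poisson draw.
#' @param interaction_kt Optional distal/distal+ interference term (kT):
#'   when non-zero, the true expression of three-operator variants with two
#'   bindable upstream sites deviates from the fitted model family (default
#'   0, off).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(barcodes_per_variant = 10, dna_depth = 1e6,
                       rna_depth = 1e6, dispersion = 10,
                       replicate_noise_cv = 0.1, n_controls = 30,
                       n_replicates = 2, interaction_kt = 0,
                       fixed_barcodes = FALSE, seed = 1) {
  stopifnot(
    dna_depth > 0, rna_depth > 0, dispersion > 0,
    barcodes_per_variant >= 1, n_replicates >= 1, n_controls >= 0
  )
  structure(
    list(
      barcodes_per_variant = barcodes_per_variant, dna_depth = dna_depth,
      rna_depth = rna_depth, dispersion = dispersion,
      replicate_noise_cv = replicate_noise_cv, n_controls = n_controls,
      n_replicates = n_replicates, interaction_kt = interaction_kt,
      fixed_barcodes = fixed_barcodes, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw ground-truth thermodynamic parameters
#'
#' Energies are drawn uniformly within per-family bounds chosen to span the
#' regime the combinatorial libraries probe and where the data can identify
#' them: core (-35,-10) and operator energies uniform on -3..3 kT (cores much
#' stronger than about -3 kT saturate every partition sum and leave only an
#' upper energy bound identifiable), looping energy on -4..-1 kT, IPTG
#' penalty on 2..4 kT. The scrambled
#' operator is always pinned non-binding (+Inf) and r_min < r_max is
#' enforced (r_min = 1, r_max uniform on 200..400 expression units).
#'
#' @param seed Integer seed.
#' @param operators Operator names to draw energies for (default: the ten
#'   operators of the two-operator combinatorial design).
#' @param core_pairs Names of the (-35,-10) pairs (default: the shipped 4x4
#'   element sets).
#' @return A [thermo_params()] object.
#' @export
sample_ground_truth <- function(seed, operators = TEN_OPERATORS,
                                core_pairs = NULL) {
  core_pairs <- core_pairs %||% as.vector(outer(
    MINUS35_SET, MINUS10_SET, function(a, b) paste0(a, ":", b)
  ))
  withr_seed(seed, {
    e_core <- setNames(runif(length(core_pairs), -3, 3), core_pairs)
    e_prox <- setNames(runif(length(operators), -3, 3), operators)
    e_dist <- setNames(runif(length(operators), -3, 3), operators)
    e_prox["O_scram"] <- Inf
    e_dist["O_scram"] <- Inf
    thermo_params(
      e_core = e_core, e_prox = e_prox, e_dist = e_dist,
      e_loop = runif(1, -4, -1), delta_iptg = runif(1, 2, 4),
      r_max = runif(1, 200, 400), r_min = 1
    )
  })
}

#' True model expression, with optional distal/distal+ interaction
#'
#' @noRd
true_expression <- function(designs, params, induced, interaction_kt = 0) {
  expr <- predict_expression(designs, params, induced = induced)$expression
  if (interaction_kt != 0 && "distalplus_op" %in% names(designs)) {
    # interference between adjacent upstream sites: variants where both the
    # distal and distal+ operators can bind deviate from the additive model
    both <- !is.na(designs$distalplus_op) &
      is.finite(params$e_dist[designs$distal_op]) &
      is.finite(params$e_dist[designs$distalplus_op])
    both[is.na(both)] <- FALSE
    expr[both] <- pmin(
      params$r_max,
      expr[both] * exp(interaction_kt * params$e_dist[designs$distal_op[both]] /
                         max(abs(params$e_dist[is.finite(params$e_dist)])))
    )
  }
  expr
}

#' Simulate a complete MPRA experiment
#'
#' For every variant the true expression per condition is the thermodynamic
#' model prediction times a lognormal variant x replicate effect. Each
#' variant gets a truncated-Poisson number of barcodes with Gamma-distributed
#' propensities; DNA counts follow the propensity and RNA counts the
#' propensity times expression, both multinomially sampled at the configured
#' depth over Gamma-mixed (negative-binomial-like) rates. Dedicated
#' scrambled-operator control promoters expressing at the background rate
#' r_min are appended.
#'
#' @param designs Library manifest from [enumerate_library()].
#' @param config A [sim_config()].
#' @param params Ground truth [thermo_params()]; defaults to
#'   `sample_ground_truth(config$seed)`.
#' @return A list: `counts` (barcode count tibble ready for
#'   [process_counts()]), `truth` (per-variant true expression per
#'   condition), `params`, `control_ids`.
#' @export
simulate_counts <- function(designs, config = sim_config(), params = NULL) {
  if (nrow(designs) == 0L) abort("designs manifest is empty")
  params <- params %||% sample_ground_truth(config$seed)
  withr_seed(config$seed + 7L, {
    truth <- dplyr::bind_rows(
      tibble::tibble(
        variant_id = designs$variant_id, condition = "uninduced",
        true_expression = true_expression(designs, params, FALSE, config$interaction_kt)
      ),
      tibble::tibble(
        variant_id = designs$variant_id, condition = "induced",
        true_expression = true_expression(designs, params, TRUE, config$interaction_kt)
      )
    )
    control_ids <- character(0)
    if (config$n_controls > 0L) {
      control_ids <- sprintf("control:neg_%03d", seq_len(config$n_controls))
      truth <- dplyr::bind_rows(
        truth,
        tidyr::expand_grid(
          variant_id = control_ids, condition = c("uninduced", "induced")
        ) |>
          dplyr::mutate(true_expression = params$r_min)
      )
    }
    all_ids <- unique(truth$variant_id)
    n_bc <- if (isTRUE(config$fixed_barcodes)) {
      rep(as.integer(config$barcodes_per_variant), length(all_ids))
    } else {
      truncated_poisson(length(all_ids), config$barcodes_per_variant)
    }
    bc_tbl <- tibble::tibble(
      variant_id = rep(all_ids, n_bc),
      barcode = sprintf("bc%06d", seq_len(sum(n_bc))),
      propensity = rgamma(sum(n_bc), shape = 4, rate = 4)
    )
    truth_wide <- truth |>
      tidyr::pivot_wider(names_from = "condition", values_from = "true_expression")

    samples <- tidyr::expand_grid(
      condition = c("uninduced", "induced"),
      replicate = seq_len(config$n_replicates),
      assay = c("DNA", "RNA")
    )
    counts <- purrr::pmap(samples, function(condition, replicate, assay) {
      e <- truth_wide[[condition]][match(bc_tbl$variant_id, truth_wide$variant_id)]
      # variant x replicate lognormal effect, shared by both assays via the
      # replicate-specific RNG substream
      sdlog <- sqrt(log(1 + config$replicate_noise_cv^2))
      rep_effect <- withr_seed(
        config$seed + 131L * replicate + 17L * (condition == "induced"),
        rlnorm(nrow(truth_wide), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      )[match(bc_tbl$variant_id, truth_wide$variant_id)]
      mu <- if (assay == "DNA") bc_tbl$propensity else bc_tbl$propensity * e * rep_effect
      depth <- if (assay == "DNA") config$dna_depth else config$rna_depth
      # negative binomial as a Gamma-Poisson mixture, conditioned on the
      # sample total: Gamma-perturbed rates fed to a multinomial draw
      lambda <- rgamma(length(mu), shape = config$dispersion,
                       rate = config$dispersion / pmax(mu, 1e-12))
      tibble::tibble(
        barcode = bc_tbl$barcode, variant_id = bc_tbl$variant_id,
        condition = condition, replicate = replicate, assay = assay,
        count = as.integer(rmultinom(1, size = depth, prob = lambda))
      )
    })
    list(
      counts = dplyr::bind_rows(counts),
      truth = truth,
      params = params,
      control_ids = control_ids
    )
  })
}

truncated_poisson <- function(n, mean) {
  if (mean <= 1) return(rep(1L, n))
  # zero-truncated Poisson via inverse-cdf on the conditional distribution
  lambda <- mean # close enough for the truncation levels used here
  out <- stats::qpois(
    stats::runif(n, stats::dpois(0, lambda), 1), lambda
  )
  pmax(out, 1L)
}

#' Write a ready-made synthetic fixture to disk
#'
#' `tiny` is a 40-variant, 3-barcode design for fast unit-level work;
#' `paper_like` is the full two-operator (1600) plus three-operator (2000)
#' design at default depth.
#'
#' @param scale `"tiny"` or `"paper_like"`.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the list of files written (counts.tsv, manifest.tsv,
#'   truth.tsv, truth_params.json).
#' @export
make_fixture <- function(scale = c("tiny", "paper_like"), dir, seed = 1) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (scale == "tiny") {
    designs <- enumerate_library("pcombo", assemble = FALSE) |>
      dplyr::filter(
        .data$distal_op %in% c("O_1", "O_scram"),
        .data$minus35 == "TTGACA",
        .data$minus10 %in% c("TATAAT", "TATGTT")
      ) # 10 proximal x 2 distal x 2 cores = 40 variants
    config <- sim_config(
      barcodes_per_variant = 3, dna_depth = 1e5, rna_depth = 1e5,
      n_controls = 8, fixed_barcodes = TRUE, seed = seed
    )
  } else {
    designs <- dplyr::bind_rows(
      enumerate_library("pcombo", assemble = FALSE),
      enumerate_library("pmultiple", assemble = FALSE)
    )
    config <- sim_config(seed = seed)
  }
  sim <- simulate_counts(designs, config)
  readr::write_tsv(sim$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(designs, file.path(dir, "manifest.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_params_json(sim$params, file.path(dir, "truth_params.json"))
  writeLines(sim$control_ids, file.path(dir, "controls.txt"))
  invisible(file.path(dir, c(
    "counts.tsv", "manifest.tsv", "truth.tsv", "truth_params.json", "controls.txt"
  )))
}

#' Serialise / read thermodynamic parameters as JSON
#'
#' Flat name-to-value maps per parameter family; `Inf` energies are stored
#' as the string `"Inf"`.
#'
#' @param params A [thermo_params()] object.
#' @param path File path.
#' @return `write_params_json` returns `path` invisibly; `read_params_json`
#'   returns a [thermo_params()] object.
#' @export
write_params_json <- function(params, path) {
  enc <- function(x) {
    out <- as.list(x)
    out[!is.finite(unlist(out))] <- "Inf"
    out
  }
  jsonlite::write_json(
    list(
      e_core = enc(params$e_core), e_prox = enc(params$e_prox),
      e_dist = enc(params$e_dist), e_loop = params$e_loop,
      delta_iptg = params$delta_iptg, r_max = params$r_max,
      r_min = params$r_min
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path)
  dec <- function(v) setNames(vapply(v, function(e) {
    if (identical(e, "Inf")) Inf else as.numeric(e)
  }, numeric(1)), names(v))
  thermo_params(
    e_core = dec(x$e_core), e_prox = dec(x$e_prox), e_dist = dec(x$e_dist),
    e_loop = x$e_loop, delta_iptg = x$delta_iptg,
    r_max = x$r_max, r_min = x$r_min
  )
}
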