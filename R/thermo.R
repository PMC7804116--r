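# Statistical-mechanics model of promoter occupancy. Each promoter state is a
# combination of RNAP binding (R), proximal LacI binding (P), distal LacI
# binding (D), distal+ LacI binding (Dp, three-operator architecture only)
# and a repression loop (L) in which LacI bound at the proximal site tethers
# a distal or distal+ site, occluding RNAP. A state's Boltzmann weight is
# exp(-E) with E the sum of the bound elements' free energies (kT units,
# lower = stronger binding), the looping energy, and an IPTG penalty per
# bound LacI unit when induced. States with RNAP bound and the proximal site
# free transcribe at r_max; all other states at the background rate r_min.

#' Thermodynamic model parameters
#'
#' Bundles all free energies (in kT; lower = stronger binding, `Inf` = a site
#' that cannot bind, e.g. a scrambled operator) and the expression rates of
#' the model.
#'
#' @param e_core Named numeric: RNAP binding energy per (-35,-10) pair. Names
#'   are `"<minus35>:<minus10>"`.
#' @param e_prox,e_dist Named numeric: LacI binding energy per operator in the
#'   proximal and distal positions. Distal+ slots reuse `e_dist` of the same
#'   operator sequence.
#' @param e_loop Looping free energy (kT) paid when a proximal-distal loop
#'   forms.
#' @param delta_iptg Non-negative energy penalty (kT) added per bound LacI
#'   unit in the presence of IPTG, weakening effective operator binding.
#' @param r_max Expression rate of transcriptionally active states
#'   (arbitrary expression units, > 0).
#' @param r_min Background rate of all other states (`0 <= r_min <= r_max`;
#'   simulation and fitting use strictly positive rates, the degenerate
#'   values are allowed for model-limit checks).
#' @return A `thermo_params` object.
#' @examples
#' p <- thermo_params(
#'   e_core = c("TTGACA:TATAAT" = -4),
#'   e_prox = c(O_1 = -1, O_scram = Inf),
#'   e_dist = c(O_1 = -0.23, O_scram = Inf),
#'   e_loop = -3, delta_iptg = 3, r_max = 300, r_min = 1
#' )
#' @export
thermo_params <- function(e_core, e_prox, e_dist, e_loop, delta_iptg,
                          r_max, r_min) {
  stopifnot(
    is.numeric(e_core), !is.null(names(e_core)),
    is.numeric(e_prox), !is.null(names(e_prox)),
    is.numeric(e_dist), !is.null(names(e_dist)),
    length(e_loop) == 1L, length(delta_iptg) == 1L
  )
  if (any(is.na(c(e_core, e_prox, e_dist, e_loop, delta_iptg)))) {
    abort("thermo_params energies must be finite or +Inf, not NA")
  }
  if (delta_iptg < 0) abort("delta_iptg must be non-negative")
  if (!(r_min >= 0 && r_max > 0)) abort("rates must be non-negative with r_max > 0")
  if (r_min > r_max) abort("r_min must not exceed r_max")
  structure(
    list(
      e_core = e_core, e_prox = e_prox, e_dist = e_dist,
      e_loop = as.numeric(e_loop), delta_iptg = as.numeric(delta_iptg),
      r_max = as.numeric(r_max), r_min = as.numeric(r_min)
    ),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>\n")
  cat("  e_core:", length(x$e_core), "(-35,-10) pairs in [",
      round(min(x$e_core), 2), ",", round(max(x$e_core), 2), "] kT\n")
  cat("  e_prox:", length(x$e_prox), "operators;  e_dist:",
      length(x$e_dist), "operators\n")
  cat("  e_loop:", round(x$e_loop, 3), "kT   delta_iptg:",
      round(x$delta_iptg, 3), "kT\n")
  cat("  r_max:", signif(x$r_max, 4), "  r_min:", signif(x$r_min, 4), "\n")
  invisible(x)
}

#' Enumerate promoter occupancy states
#'
#' Lists every allowed occupancy state of the model. For the two-operator
#' architecture these are all 8 combinations of RNAP/proximal/distal binding
#' plus the looped state, 9 in total. The three-operator architecture has all
#' 16 binding combinations plus 4 looped states (loop to the distal site with
#' the distal+ site free or bound, and loop to the distal+ site with the
#' distal site free or bound), 20 in total. A loop requires the proximal site
#' and its partner to be bound and excludes RNAP; at most one loop forms.
#'
#' @param architecture `"two_operator"` or `"three_operator"`.
#' @return A tibble with logical columns `R`, `P`, `D` (and `Dp`), integer
#'   `L` and `loop_partner` (`NA`, `"distal"` or `"distalplus"`).
#' @examples
#' nrow(enumerate_states("two_operator")) # 9
#' @export
enumerate_states <- function(architecture = c("two_operator", "three_operator")) {
  architecture <- match.arg(architecture)
  three <- architecture == "three_operator"
  grid <- tidyr::expand_grid(
    R = c(FALSE, TRUE), P = c(FALSE, TRUE), D = c(FALSE, TRUE),
    Dp = if (three) c(FALSE, TRUE) else FALSE,
    loop_partner = c(NA_character_, "distal", if (three) "distalplus")
  )
  keep <- is.na(grid$loop_partner) |
    (!grid$R & grid$P &
       ifelse(grid$loop_partner == "distal", grid$D, grid$Dp))
  keep[is.na(keep)] <- TRUE
  states <- grid[keep, ]
  states$L <- as.integer(!is.na(states$loop_partner))
  if (!three) states$Dp <- NULL
  dplyr::arrange(states, .data$L, .data$R, .data$P, .data$D)
}

#' Boltzmann weight of occupancy states
#'
#' Computes `exp(-E)` for each state, where `E` sums the core, proximal,
#' distal (and distal+) binding energies of the bound elements, the loop
#' energy for looped states, and `delta_iptg` per bound LacI unit when
#' `induced = TRUE`. A `+Inf` energy gives weight exactly 0.
#'
#' @param states State tibble from [enumerate_states()].
#' @param params A [thermo_params()] object. For this per-state view a single
#'   energy per family is used: the first element of `e_core`, `e_prox`,
#'   `e_dist` (plus `e_distplus` below).
#' @param induced Logical: IPTG present?
#' @param e_core,e_prox,e_dist,e_distplus Optional scalar energy overrides.
#' @return Numeric vector of non-negative weights, one per state.
#' @export
state_weight <- function(states, params, induced = FALSE,
                         e_core = NULL, e_prox = NULL, e_dist = NULL,
                         e_distplus = NULL) {
  ec <- e_core %||% params$e_core[[1]]
  ep <- e_prox %||% params$e_prox[[1]]
  ed <- e_dist %||% params$e_dist[[1]]
  eq <- e_distplus %||% ed
  has_dp <- "Dp" %in% names(states)
  dp <- if (has_dp) states$Dp else FALSE
  n_laci <- states$P + states$D + dp
  energy <- states$R * ec + states$P * ep + states$D * ed + dp * eq +
    states$L * params$e_loop +
    (if (induced) params$delta_iptg else 0) * n_laci
  # R * Inf with R = 0 must contribute 0, not NaN
  energy[is.nan(energy)] <- Inf
  exp(-energy)
}

# vectorised closed-form partition-function pieces --------------------------

# returns list(Z, Z_active): ep/ed/eq already include any IPTG penalty shift
partition_two <- function(wc, wp, wd, wl) {
  list(
    Z = (1 + wc) * (1 + wp) * (1 + wd) + wp * wd * wl,
    Z_active = wc * (1 + wd)
  )
}

partition_three <- function(wc, wp, wd, wq, wl) {
  list(
    Z = (1 + wc) * (1 + wp) * (1 + wd) * (1 + wq) +
      wp * wl * (wd * (1 + wq) + wq * (1 + wd)),
    Z_active = wc * (1 + wd) * (1 + wq)
  )
}

variant_energies <- function(variants, params) {
  if (is.character(variants)) {
    abort("`variants` must be a manifest tibble with part columns")
  }
  core_key <- paste0(variants$minus35, ":", variants$minus10)
  if (all(is.na(variants$minus35)) && "core_pair" %in% names(variants)) {
    core_key <- variants$core_pair
  }
  lookup <- function(values, table, family) {
    idx <- match(values, names(table))
    miss <- unique(values[is.na(idx) & !is.na(values)])
    if (length(miss) > 0L) {
      abort(paste0(
        "no ", family, " energy for: ", paste(miss, collapse = ", ")
      ))
    }
    out <- unname(table[idx])
    out[is.na(values)] <- Inf # an absent part cannot bind
    out
  }
  list(
    ec = lookup(core_key, params$e_core, "core (-35:-10)"),
    ep = lookup(variants$proximal_op, params$e_prox, "proximal operator"),
    ed = lookup(variants$distal_op, params$e_dist, "distal operator"),
    eq = if ("distalplus_op" %in% names(variants)) {
      lookup(variants$distalplus_op, params$e_dist, "distal (reused for distal+) operator")
    } else {
      rep(Inf, nrow(variants))
    },
    three = !all(is.na(variants$distalplus_op %||% NA))
  )
}

#' Predict expression from the thermodynamic model
#'
#' Expression is the state-probability-weighted rate
#' `(r_min * Z + (r_max - r_min) * Z_active) / Z`, where `Z_active` sums the
#' Boltzmann weights of states with RNAP bound and the proximal operator
#' free. It always lies in `[r_min, r_max]`.
#'
#' @param variants A library manifest tibble (columns `variant_id`,
#'   `proximal_op`, `distal_op`, `distalplus_op`, `minus35`, `minus10`);
#'   variants with a non-missing `distalplus_op` use the three-operator state
#'   space.
#' @param params A [thermo_params()] object.
#' @param induced Logical: predict in the IPTG-induced condition?
#' @return The manifest with an added `expression` column (and `condition`).
#' @examples
#' p <- thermo_params(
#'   e_core = c("TTGACA:TATAAT" = 0), e_prox = c(O_1 = 0),
#'   e_dist = c(O_1 = 0), e_loop = 0, delta_iptg = 0, r_max = 1, r_min = 1e-9
#' )
#' v <- tibble::tibble(
#'   variant_id = "v1", proximal_op = "O_1", distal_op = "O_1",
#'   distalplus_op = NA_character_, minus35 = "TTGACA", minus10 = "TATAAT"
#' )
#' predict_expression(v, p)$expression # ~ 2/9
#' @export
predict_expression <- function(variants, params, induced = FALSE) {
  e <- variant_energies(variants, params)
  shift <- if (induced) params$delta_iptg else 0
  wc <- exp(-e$ec)
  wp <- exp(-(e$ep + shift))
  wd <- exp(-(e$ed + shift))
  wl <- exp(-params$e_loop)
  if (e$three) {
    wq <- exp(-(e$eq + shift))
    z <- partition_three(wc, wp, wd, wq, wl)
  } else {
    z <- partition_two(wc, wp, wd, wl)
  }
  out <- variants
  out$condition <- if (induced) "induced" else "uninduced"
  out$expression <- params$r_min + (params$r_max - params$r_min) * z$Z_active / z$Z
  out
}

#' Predict induction fold change
#'
#' Fold change is the ratio of model expression with IPTG to model expression
#' without. It is always >= 1 when `delta_iptg >= 0` and exactly 1 when
#' `delta_iptg = 0` or when no operator can bind.
#'
#' @inheritParams predict_expression
#' @return The manifest with added `fold_change`.
#' @export
predict_fold_change <- function(variants, params) {
  out <- variants
  out$fold_change <- predict_expression(variants, params, induced = TRUE)$expression /
    predict_expression(variants, params, induced = FALSE)$expression
  out
}

#' Expression and fold-change landscape over operator binding energies
#'
#' Evaluates the model on a grid of proximal and distal operator energies at
#' a fixed core, giving the induced/uninduced expression surfaces and the
#' fold-change landscape.
#'
#' @param params A [thermo_params()] object; `r_max`, `r_min`, `e_loop` and
#'   `delta_iptg` are taken from it.
#' @param e_prox,e_dist Numeric grids of proximal/distal energies (kT).
#' @param e_core Scalar core energy (kT) held fixed.
#' @return A tibble with one row per grid point: `e_prox`, `e_dist`,
#'   `uninduced`, `induced`, `fold_change`.
#' @export
expression_grid <- function(params, e_prox, e_dist, e_core) {
  if (length(e_prox) == 0L || length(e_dist) == 0L) abort("empty energy grid")
  g <- tidyr::expand_grid(e_prox = e_prox, e_dist = e_dist)
  wl <- exp(-params$e_loop)
  wc <- exp(-e_core)
  eval_cond <- function(shift) {
    z <- partition_two(wc, exp(-(g$e_prox + shift)), exp(-(g$e_dist + shift)), wl)
    params$r_min + (params$r_max - params$r_min) * z$Z_active / z$Z
  }
  g$uninduced <- eval_cond(0)
  g$induced <- eval_cond(params$delta_iptg)
  g$fold_change <- g$induced / g$uninduced
  g
}
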