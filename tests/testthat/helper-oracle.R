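# Independent exhaustive-enumeration oracle for the occupancy model.
# Deliberately written as plain loops over raw occupancy tuples, with no use
# of the package's partition-function code, so it can stand as an
# independent check of predict_expression().

oracle_enumerate <- function(architecture) {
  three <- architecture == "three_operator"
  states <- list()
  for (R in c(0, 1)) {
    for (P in c(0, 1)) {
      for (D in c(0, 1)) {
        for (Dp in if (three) c(0, 1) else 0) {
          for (partner in c(NA, "distal", if (three) "distalplus")) {
            if (!is.na(partner)) {
              # a loop needs the proximal site plus its partner bound, and
              # excludes RNAP
              if (R == 1 || P == 0) next
              if (partner == "distal" && D == 0) next
              if (partner == "distalplus" && Dp == 0) next
            }
            states[[length(states) + 1]] <- list(
              R = R, P = P, D = D, Dp = Dp, partner = partner
            )
          }
        }
      }
    }
  }
  states
}

oracle_state_energy <- function(s, ec, ep, ed, eq, el, delta, induced) {
  e <- 0
  if (s$R == 1) e <- e + ec
  if (s$P == 1) e <- e + ep
  if (s$D == 1) e <- e + ed
  if (s$Dp == 1) e <- e + eq
  if (!is.na(s$partner)) e <- e + el
  if (induced) e <- e + delta * (s$P + s$D + s$Dp)
  e
}

oracle_expression <- function(architecture, ec, ep, ed, eq = Inf, el, delta,
                              r_max, r_min, induced) {
  states <- oracle_enumerate(architecture)
  z <- 0
  z_active <- 0
  for (s in states) {
    w <- exp(-oracle_state_energy(s, ec, ep, ed, eq, el, delta, induced))
    z <- z + w
    if (s$R == 1 && s$P == 0) z_active <- z_active + w
  }
  (r_min * z + (r_max - r_min) * z_active) / z
}

# random finite parameter draw for property tests
oracle_random_draw <- function() {
  list(
    ec = runif(1, -6, 6), ep = runif(1, -6, 6), ed = runif(1, -6, 6),
    eq = runif(1, -6, 6), el = runif(1, -6, 2), delta = runif(1, 0, 6),
    r_max = runif(1, 10, 500), r_min = runif(1, 0.01, 5)
  )
}

# package-side single-variant prediction for comparison with the oracle
pkg_expression <- function(architecture, d, induced) {
  params <- thermo_params(
    e_core = c("m35:m10" = d$ec), e_prox = c(OP = d$ep),
    e_dist = c(OD = d$ed, OQ = d$eq), e_loop = d$el,
    delta_iptg = d$delta, r_max = d$r_max, r_min = min(d$r_min, d$r_max)
  )
  v <- tibble::tibble(
    variant_id = "v", proximal_op = "OP", distal_op = "OD",
    distalplus_op = if (architecture == "three_operator") "OQ" else NA_character_,
    minus35 = "m35", minus10 = "m10"
  )
  predict_expression(v, params, induced = induced)$expression
}
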