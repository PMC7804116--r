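# Downstream analyses: relative-expression spacing profiles with loess
# smoothing and helical-phase annotation, a cosine periodicity statistic,
# fold-change landscape optima, and the routine group comparisons.

#' Expression relative to a reference variant
#'
#' Ratio of final (control-normalised, replicate-averaged) expression of each
#' variant to that of a reference variant, e.g. the promoter without a
#' repressor site, or the proximal-only variant of a spacing series.
#'
#' @param expr Replicate-averaged expression tibble (`variant_id`,
#'   `condition`, `expression`).
#' @param reference_variant `variant_id` of the reference.
#' @return The table with an added `relative_expression` column.
#' @export
relative_expression <- function(expr, reference_variant) {
  ref <- expr[expr$variant_id == reference_variant, c("condition", "expression")]
  if (nrow(ref) == 0L) {
    abort(sprintf("reference variant '%s' not found", reference_variant))
  }
  names(ref)[2] <- ".ref"
  out <- dplyr::left_join(expr, ref, by = "condition")
  out$relative_expression <- out$expression / out$.ref
  out$.ref <- NULL
  out
}

#' Loess-smoothed spacing profile
#'
#' Locally weighted polynomial regression (degree 2, tricube weights) of
#' relative expression against distal-site position, evaluated at each
#' observed position — the standard smooth drawn through operator-spacing
#' series.
#'
#' @param profile Tibble with columns `position` and `value`.
#' @param span Loess span (default 0.5).
#' @param degree Local polynomial degree (default 2).
#' @return The profile with an added `smoothed` column, ordered by position.
#' @export
loess_profile <- function(profile, span = 0.5, degree = 2) {
  stopifnot(all(c("position", "value") %in% names(profile)))
  if (nrow(profile) < 10L) abort("need at least 10 positions to smooth")
  out <- dplyr::arrange(profile, .data$position)
  fit <- tryCatch(
    loess(value ~ position, data = out, span = span, degree = degree,
          family = "gaussian", surface = "direct"),
    error = function(e) abort(paste0("loess failed (span too small?): ", conditionMessage(e)))
  )
  out$smoothed <- as.numeric(predict(fit, newdata = out))
  out
}

#' Helical-phase annotation of distal positions
#'
#' Flags positions whose centre-to-centre spacing from the proximal site is
#' within `window / 2` of a whole number of helical turns (B-DNA period
#' 10.5 bp), i.e. the 3 bp windows in which the two operators sit on the
#' same face of the helix and looping is geometrically favourable.
#'
#' @param positions Integer vector of distal-site centres (TSS coordinates,
#'   no position 0).
#' @param proximal_center Proximal-site centre (default +12, the spacing
#'   design).
#' @param period Helical period in bp (default 10.5).
#' @param window In-phase window width in bp (default 3).
#' @return Tibble with `position`, `spacing` (centre-to-centre, bp) and
#'   `in_phase`.
#' @export
phase_annotation <- function(positions, proximal_center = 12L, period = 10.5,
                             window = 3) {
  spacing <- vapply(
    as.integer(positions), axis_distance, numeric(1),
    b = as.integer(proximal_center)
  )
  frac <- spacing %% period
  dist_to_turn <- pmin(frac, period - frac)
  tibble::tibble(
    position = positions, spacing = spacing,
    in_phase = dist_to_turn <= window / 2
  )
}

#' Cosine periodicity fit with permutation test
#'
#' Quantifies the helical periodicity of a spacing profile by least-squares
#' cosine regression with the period free on a grid (default 9-12 bp),
#' testing amplitude significance by permuting position labels. This is a
#' construction of this package: it turns the qualitative 10-11 bp
#' periodicity of looping-mediated repression into a test statistic.
#'
#' @param profile Tibble with `position` and `value` columns spanning at
#'   least two full periods.
#' @param period_range Period search range in bp (default `c(9, 12)`).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Permutation seed.
#' @return A list: `amplitude`, `phase` (radians), `period` (bp), `p_value`
#'   and the fitted `curve` tibble.
#' @export
periodicity_fit <- function(profile, period_range = c(9, 12), n_perm = 1000,
                            seed = 1) {
  stopifnot(all(c("position", "value") %in% names(profile)))
  x <- as.numeric(profile$position)
  y <- profile$value
  if (diff(range(x)) < 2 * period_range[1]) {
    abort("profile spans fewer than two periods")
  }
  periods <- seq(period_range[1], period_range[2], by = 0.1)
  fit_amp <- function(yy) {
    best <- c(amplitude = 0, phase = 0, period = periods[1], rss = Inf)
    for (p in periods) {
      basis <- cbind(1, cos(2 * pi * x / p), sin(2 * pi * x / p))
      co <- qr.coef(qr(basis), yy)
      rss <- sum((yy - basis %*% co)^2)
      if (rss < best["rss"]) {
        best <- c(
          amplitude = sqrt(co[2]^2 + co[3]^2),
          phase = atan2(-co[3], co[2]), period = p, rss = rss
        )
      }
    }
    best
  }
  obs <- fit_amp(y)
  perm_amp <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) fit_amp(sample(y))["amplitude"], numeric(1))
  })
  p_best <- obs[["period"]]
  basis <- cbind(1, cos(2 * pi * x / p_best), sin(2 * pi * x / p_best))
  co <- qr.coef(qr(basis), y)
  list(
    amplitude = obs[["amplitude"]], phase = obs[["phase"]],
    period = p_best,
    p_value = (1 + sum(perm_amp >= obs[["amplitude"]])) / (1 + n_perm),
    curve = tibble::tibble(position = x, value = y, fitted = as.numeric(basis %*% co))
  )
}

#' Locate the fold-change optimum on an operator-energy grid
#'
#' Grid search of the model fold change over proximal and distal operator
#' energies at a fixed core strength. Reports whether the maximum sits on
#' the grid edge (in which case the grid does not cover the optimum).
#'
#' @param params A [thermo_params()] object (rates, loop and IPTG penalty
#'   are taken from it).
#' @param e_core Core energy (kT) held fixed.
#' @param e_prox,e_dist Energy grids (kT); defaults span -6 to 6 kT in 0.1
#'   steps.
#' @return A list: `e_prox_opt`, `e_dist_opt`, `fc_max`, `on_edge`,
#'   `degenerate` (fold change flat, e.g. `delta_iptg = 0`), and the full
#'   `grid`.
#' @export
fold_change_optimum <- function(params, e_core,
                                e_prox = seq(-6, 6, by = 0.1),
                                e_dist = seq(-6, 6, by = 0.1)) {
  grid <- expression_grid(params, e_prox = e_prox, e_dist = e_dist, e_core = e_core)
  i <- which.max(grid$fold_change)
  fc_range <- diff(range(grid$fold_change))
  on_edge <- (length(e_prox) > 1L && grid$e_prox[i] %in% range(e_prox)) ||
    (length(e_dist) > 1L && grid$e_dist[i] %in% range(e_dist))
  degenerate <- fc_range < 1e-9
  if (on_edge && !degenerate) {
    warn("fold-change optimum lies on the grid edge; widen the energy grid")
  }
  list(
    e_prox_opt = grid$e_prox[i], e_dist_opt = grid$e_dist[i],
    fc_max = grid$fold_change[i], on_edge = on_edge,
    degenerate = degenerate, grid = grid
  )
}

#' Group comparisons for expression tables
#'
#' Thin wrappers over the routine tests used to compare promoter groups:
#' Welch's two-sided t test or the two-sided Mann-Whitney U test on all group
#' pairs with optional Benjamini-Hochberg correction, or a linear-model
#' F test (`test = "anova"`) of expression against a continuous covariate
#' such as operator spacing.
#'
#' @param data Tibble of observations.
#' @param value Name of the value column.
#' @param group Name of the grouping (or covariate, for `"anova"`) column.
#' @param test `"welch_t"`, `"mann_whitney"` or `"anova"`.
#' @param correction `"benjamini_hochberg"` or `"none"`.
#' @return A tibble with one row per comparison: groups, statistic, `p_value`
#'   and `p_adjusted`.
#' @export
compare_groups <- function(data, value, group,
                           test = c("welch_t", "mann_whitney", "anova"),
                           correction = c("benjamini_hochberg", "none")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  v <- data[[value]]
  g <- data[[group]]
  if (test == "anova") {
    fit <- lm(v ~ g)
    a <- stats::anova(fit)
    out <- tibble::tibble(
      group1 = group, group2 = "(slope)",
      statistic = a$`F value`[1], p_value = a$`Pr(>F)`[1]
    )
  } else {
    groups <- unique(as.character(g))
    if (length(groups) < 2L) abort("need at least two groups")
    sizes <- table(as.character(g))
    if (any(sizes < 2L)) abort("every group needs at least 2 observations")
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    out <- purrr::map_dfr(pairs, function(pr) {
      xa <- v[g == pr[1]]
      xb <- v[g == pr[2]]
      res <- if (test == "welch_t") {
        t.test(xa, xb, alternative = "two.sided", var.equal = FALSE)
      } else {
        suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided"))
      }
      tibble::tibble(
        group1 = pr[1], group2 = pr[2],
        statistic = unname(res$statistic), p_value = res$p.value
      )
    })
  }
  out$p_adjusted <- if (correction == "benjamini_hochberg") {
    p.adjust(out$p_value, method = "BH")
  } else {
    out$p_value
  }
  out
}
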