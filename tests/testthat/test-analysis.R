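test_that("relative expression is a ratio to the reference variant", {
  expr <- tibble::tibble(
    variant_id = c("a", "b", "ref"),
    condition = "uninduced",
    expression = c(0.5, 2, 1)
  )
  out <- relative_expression(expr, "ref")
  expect_equal(out$relative_expression, c(0.5, 2, 1))
  expect_equal(out$relative_expression[out$variant_id == "ref"], 1)
  # reciprocal property: ratio(a|b) * ratio(b|a) = 1
  ra <- relative_expression(expr, "a")$relative_expression[2]
  rb <- relative_expression(expr, "b")$relative_expression[1]
  expect_equal(ra * rb, 1)
  expect_error(relative_expression(expr, "missing"), "not found")
})

test_that("loess smoothing is exact on polynomial profiles", {
  pos <- -(83:116)
  const <- tibble::tibble(position = pos, value = 3)
  expect_equal(loess_profile(const)$smoothed, rep(3, length(pos)), tolerance = 1e-8)

  lin <- tibble::tibble(position = pos, value = 0.2 * pos + 1)
  out <- loess_profile(lin)
  expect_equal(out$smoothed, out$value, tolerance = 1e-6)

  set.seed(3)
  noisy <- tibble::tibble(
    position = pos,
    value = cos(2 * pi * pos / 10.5) + rnorm(length(pos), sd = 0.3)
  )
  sm <- loess_profile(noisy, span = 0.3)
  clean <- cos(2 * pi * sm$position / 10.5)
  expect_lt(var(sm$smoothed - clean), var(sm$value - clean))
  expect_error(loess_profile(const[1:5, ]), "10 positions")
})

test_that("helical phase annotation flags whole-turn spacings", {
  # spacings of exactly k * 10.5 bp are in phase
  prox <- 12L
  k_turns <- c(5, 8, 10)
  positions <- vapply(k_turns, function(k) {
    p <- prox - round(k * 10.5)
    if (p <= 0) p - 1L else p # gapped axis: skip position 0
  }, numeric(1))
  ann <- phase_annotation(positions, proximal_center = prox)
  expect_true(all(abs(ann$spacing %% 10.5) <= 0.5 | abs(ann$spacing %% 10.5 - 10.5) <= 0.5))
  expect_true(all(ann$in_phase))

  # half-turn offsets are out of phase
  off <- phase_annotation(positions - 5L, proximal_center = prox)
  expect_false(any(off$in_phase))

  # flags repeat with the period: shifting by 21 bp (2 turns) preserves them
  base <- phase_annotation(-(83:100), proximal_center = prox)
  shifted <- phase_annotation(-(83:100) - 21L, proximal_center = prox)
  expect_equal(base$in_phase, shifted$in_phase)
})

test_that("the cosine periodicity statistic detects a planted 10.5 bp signal", {
  pos <- -(83:116)
  pure <- tibble::tibble(position = pos, value = cos(2 * pi * pos / 10.5))
  fit <- periodicity_fit(pure, n_perm = 1000, seed = 1)
  expect_gte(fit$period, 10.4)
  expect_lte(fit$period, 10.6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_lte(fit$p_value, 0.001)

  # amplitude is invariant to a constant offset
  fit2 <- periodicity_fit(dplyr::mutate(pure, value = value + 5), n_perm = 50, seed = 1)
  expect_equal(fit2$amplitude, fit$amplitude, tolerance = 1e-6)

  # white noise: amplitude near zero relative to signal, p rarely small
  set.seed(2024)
  p_noise <- vapply(seq_len(20), function(i) {
    prof <- tibble::tibble(position = pos, value = rnorm(length(pos)))
    periodicity_fit(prof, n_perm = 200, seed = i)$p_value
  }, numeric(1))
  expect_gte(mean(p_noise > 0.05), 0.9)

  expect_error(
    periodicity_fit(tibble::tibble(position = 1:10, value = rnorm(10))),
    "two periods"
  )
})

test_that("a planted periodic signal is detected with high power at SNR 2", {
  pos <- -(83:116)
  set.seed(99)
  detected <- vapply(seq_len(20), function(i) {
    prof <- tibble::tibble(
      position = pos,
      value = cos(2 * pi * pos / 10.5) + rnorm(length(pos), sd = 0.5)
    )
    periodicity_fit(prof, n_perm = 200, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("fold-change optima are interior for strong cores and shift with core strength", {
  params <- thermo_params(
    e_core = c(core = -5), e_prox = c(X = 0), e_dist = c(X = -0.23),
    e_loop = -3, delta_iptg = 3, r_max = 300, r_min = 1
  )
  opt <- fold_change_optimum(params, e_core = -5, e_dist = -0.23)
  expect_false(opt$on_edge)
  expect_false(opt$degenerate)
  expect_gt(opt$fc_max, 1)

  # optimal proximal strength weakens monotonically as the core weakens
  opts <- vapply(
    c(-5, -3, -1),
    function(ec) fold_change_optimum(params, e_core = ec, e_dist = -0.23)$e_prox_opt,
    numeric(1)
  )
  expect_true(all(diff(opts) > 0))

  # agreement with a dense grid within one coarse step
  coarse <- fold_change_optimum(
    params, e_core = -5,
    e_prox = seq(-6, 6, 0.2), e_dist = -0.23
  )
  dense <- fold_change_optimum(
    params, e_core = -5,
    e_prox = seq(-6, 6, 0.01), e_dist = -0.23
  )
  expect_lte(abs(coarse$e_prox_opt - dense$e_prox_opt), 0.2)

  # delta_iptg = 0 degenerates to a flat unit landscape
  flat <- thermo_params(
    e_core = c(core = -5), e_prox = c(X = 0), e_dist = c(X = -0.23),
    e_loop = -3, delta_iptg = 0, r_max = 300, r_min = 1
  )
  o0 <- fold_change_optimum(flat, e_core = -5)
  expect_true(o0$degenerate)
  expect_equal(o0$fc_max, 1)
})

test_that("group comparisons wire the standard tests correctly", {
  set.seed(1)
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 10),
    y = c(rnorm(10), rnorm(10, 2), rnorm(10, 4))
  )
  out <- compare_groups(d, "y", "g", test = "welch_t")
  expect_equal(nrow(out), 3L)
  # Benjamini-Hochberg on {0.01, 0.02, 0.03} gives {0.03, 0.03, 0.03}
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  # swapping group labels leaves the two-sided p unchanged
  swapped <- d
  swapped$g <- c(rep("b", 10), rep("a", 10), rep("c", 10))
  out_s <- compare_groups(swapped, "y", "g", test = "mann_whitney")
  out_o <- compare_groups(d, "y", "g", test = "mann_whitney")
  expect_equal(sort(out_s$p_value), sort(out_o$p_value))

  # identical groups are indistinguishable
  same <- tibble::tibble(g = rep(c("a", "b"), each = 5), y = rep(1:5, 2))
  expect_gte(compare_groups(same, "y", "g", test = "mann_whitney")$p_value, 0.9)

  # linear-model F-test mode for a continuous covariate
  trend <- tibble::tibble(x = 1:30, y = 0.2 * (1:30) + rnorm(30, sd = 0.5))
  an <- compare_groups(trend, "y", "x", test = "anova")
  expect_lt(an$p_value, 0.001)

  expect_error(
    compare_groups(tibble::tibble(g = "a", y = 1), "y", "g"),
    "two groups"
  )
})

test_that("plot builders return ggplot objects", {
  params <- thermo_params(
    e_core = c(core = -4), e_prox = c(X = 0), e_dist = c(X = 0),
    e_loop = -3, delta_iptg = 3, r_max = 300, r_min = 1
  )
  grid <- expression_grid(params, seq(-3, 3, 1), seq(-3, 3, 1), e_core = -4)
  expect_s3_class(plot_landscape(grid), "ggplot")

  prof <- loess_profile(tibble::tibble(
    position = -(83:116), value = cos(2 * pi * -(83:116) / 10.5) + 1.5
  ))
  expect_s3_class(
    plot_spacing_profile(dplyr::rename(prof, value = value)), "ggplot"
  )

  designs <- small_pcombo()
  expr <- noiseless_expression(designs, small_truth())
  fit <- fit_parameters(expr, designs, fit_config(seed = 1, n_starts = 2))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(nrow(augment(fit)), nrow(expr))
})
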