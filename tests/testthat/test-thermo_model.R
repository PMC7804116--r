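test_that("state enumeration is exhaustive and duplicate-free", {
  two <- enumerate_states("two_operator")
  expect_equal(nrow(two), 9L)
  expect_equal(nrow(dplyr::distinct(two)), 9L)
  expect_equal(sum(two$L), 1L)
  # the empty reference state is present and has weight exp(0) = 1
  empty <- !two$R & !two$P & !two$D & two$L == 0
  expect_equal(sum(empty), 1L)
  p <- thermo_params(
    e_core = c(a = 2), e_prox = c(X = -1), e_dist = c(X = 3),
    e_loop = -2, delta_iptg = 1, r_max = 10, r_min = 1
  )
  expect_equal(state_weight(two, p)[empty], 1)

  three <- enumerate_states("three_operator")
  # frozen against the independent exhaustive filter over raw tuples
  expect_equal(nrow(three), length(oracle_enumerate("three_operator")))
  expect_equal(nrow(three), 20L)
  expect_equal(nrow(dplyr::distinct(three)), 20L)
  expect_error(enumerate_states("four_operator"))
})

test_that("state weights follow the Boltzmann rule", {
  s <- enumerate_states("two_operator")
  base <- thermo_params(
    e_core = c(a = 0), e_prox = c(X = 0), e_dist = c(X = 0),
    e_loop = 0, delta_iptg = 0, r_max = 1, r_min = 0
  )
  rnap_only <- s$R & !s$P & !s$D
  expect_equal(state_weight(s, base)[rnap_only], 1)
  expect_equal(
    state_weight(s, base, e_core = -1)[rnap_only], exp(1)
  )
  # proximal-bound state with E_prox = -2, delta_iptg = 3, induced: e^-1
  p <- thermo_params(
    e_core = c(a = 0), e_prox = c(X = -2), e_dist = c(X = 0),
    e_loop = 0, delta_iptg = 3, r_max = 1, r_min = 0
  )
  prox_only <- !s$R & s$P & !s$D
  expect_equal(state_weight(s, p, induced = TRUE)[prox_only], exp(-1))
  # +Inf energy gives weight exactly 0
  expect_equal(state_weight(s, p, e_prox = Inf)[prox_only], 0)
})

test_that("state probabilities are normalised over random parameter draws", {
  p0 <- thermo_params(
    e_core = c(a = 0), e_prox = c(X = 0), e_dist = c(X = 0, Q = 0),
    e_loop = 0, delta_iptg = 0, r_max = 1, r_min = 0
  )
  set.seed(101)
  for (arch in c("two_operator", "three_operator")) {
    s <- enumerate_states(arch)
    for (i in seq_len(500)) {
      d <- oracle_random_draw()
      p <- thermo_params(
        e_core = c(a = d$ec), e_prox = c(X = d$ep), e_dist = c(X = d$ed, Q = d$eq),
        e_loop = d$el, delta_iptg = d$delta, r_max = d$r_max,
        r_min = min(d$r_min, d$r_max)
      )
      w <- state_weight(s, p, induced = i %% 2 == 0, e_distplus = d$eq)
      expect_true(all(w >= 0))
      expect_equal(sum(w / sum(w)), 1, tolerance = 1e-12)
    }
  }
})

test_that("predict_expression matches the exhaustive-enumeration oracle", {
  set.seed(7)
  for (arch in c("two_operator", "three_operator")) {
    worst <- 0
    for (i in seq_len(600)) {
      d <- oracle_random_draw()
      d$r_min <- min(d$r_min, d$r_max)
      induced <- i %% 2 == 0
      expected <- oracle_expression(
        arch, d$ec, d$ep, d$ed, d$eq, d$el, d$delta, d$r_max, d$r_min, induced
      )
      got <- pkg_expression(arch, d, induced)
      worst <- max(worst, abs(got - expected) / expected)
    }
    expect_lt(worst, 1e-10)
  }
})

test_that("the worked model value and closed-form limits hold", {
  zero <- thermo_params(
    e_core = c(a = 0), e_prox = c(X = 0), e_dist = c(X = 0),
    e_loop = 0, delta_iptg = 0, r_max = 1, r_min = 0
  )
  v <- tibble::tibble(
    variant_id = "v", proximal_op = "X", distal_op = "X",
    distalplus_op = NA_character_, minus35 = "a35", minus10 = "a10"
  )
  zero$e_core <- c("a35:a10" = 0)
  # all energies 0, r_max = 1, r_min = 0: 2 active of 9 equal-weight states
  expect_equal(predict_expression(v, zero)$expression, 2 / 9)

  # both operators non-binding: two-state closed form
  for (ec in c(-3, 0, 2)) {
    p <- thermo_params(
      e_core = setNames(ec, "a35:a10"), e_prox = c(X = Inf), e_dist = c(X = Inf),
      e_loop = -2, delta_iptg = 3, r_max = 7, r_min = 0.2
    )
    expect_equal(
      predict_expression(v, p)$expression,
      (0.2 + 7 * exp(-ec)) / (1 + exp(-ec))
    )
    # no repressor: nothing for IPTG to relieve
    expect_equal(predict_fold_change(v, p)$fold_change, 1)
  }

  # degenerate rates: expression equals the common rate regardless of energies
  pc <- thermo_params(
    e_core = c("a35:a10" = -1.3), e_prox = c(X = 0.4), e_dist = c(X = -2),
    e_loop = -1, delta_iptg = 2, r_max = 5, r_min = 5
  )
  expect_equal(predict_expression(v, pc)$expression, 5)
})

test_that("fold change is 1 at delta = 0 and reaches the strong-IPTG limit", {
  v <- tibble::tibble(
    variant_id = "v", proximal_op = "X", distal_op = "X",
    distalplus_op = NA_character_, minus35 = "a", minus10 = "b"
  )
  p0 <- thermo_params(
    e_core = c("a:b" = -2), e_prox = c(X = -1), e_dist = c(X = -1),
    e_loop = -3, delta_iptg = 0, r_max = 100, r_min = 1
  )
  expect_equal(predict_fold_change(v, p0)$fold_change, 1)

  # all energies 0, r_max = 1, r_min = 0: strong IPTG drives the promoter to
  # the operator-free two-state limit, FC = (1/2) / (2/9) = 2.25
  p_inf <- thermo_params(
    e_core = c("a:b" = 0), e_prox = c(X = 0), e_dist = c(X = 0),
    e_loop = 0, delta_iptg = 1e4, r_max = 1, r_min = 0
  )
  expect_equal(predict_fold_change(v, p_inf)$fold_change, 2.25, tolerance = 1e-9)

  # FC >= 1 whenever delta_iptg >= 0 (property over random draws)
  set.seed(33)
  for (i in seq_len(300)) {
    d <- oracle_random_draw()
    p <- thermo_params(
      e_core = c("a:b" = d$ec), e_prox = c(X = d$ep), e_dist = c(X = d$ed),
      e_loop = d$el, delta_iptg = d$delta, r_max = d$r_max,
      r_min = min(d$r_min, d$r_max)
    )
    expect_gte(predict_fold_change(v, p)$fold_change, 1 - 1e-12)
  }
})

test_that("expression respects bounds and monotonicity", {
  v <- tibble::tibble(
    variant_id = "v", proximal_op = "X", distal_op = "X",
    distalplus_op = NA_character_, minus35 = "a", minus10 = "b"
  )
  set.seed(5)
  for (i in seq_len(200)) {
    d <- oracle_random_draw()
    d$r_min <- min(d$r_min, d$r_max)
    p <- thermo_params(
      e_core = c("a:b" = d$ec), e_prox = c(X = d$ep), e_dist = c(X = d$ed),
      e_loop = d$el, delta_iptg = d$delta, r_max = d$r_max, r_min = d$r_min
    )
    e <- predict_expression(v, p, induced = i %% 2 == 0)$expression
    expect_gte(e, d$r_min - 1e-12)
    expect_lte(e, d$r_max + 1e-12)
  }

  base <- thermo_params(
    e_core = c(core = -2), e_prox = c(X = 0), e_dist = c(X = 0),
    e_loop = -2, delta_iptg = 2, r_max = 100, r_min = 1
  )
  grid <- expression_grid(base, e_prox = seq(-4, 4, 0.5), e_dist = seq(-4, 4, 0.5), e_core = -2)
  # weaker repressor binding (higher energy) never lowers expression
  by_dist <- split(grid, grid$e_dist)
  for (g in by_dist) {
    g <- g[order(g$e_prox), ]
    expect_true(all(diff(g$uninduced) >= -1e-12))
  }
  by_prox <- split(grid, grid$e_prox)
  for (g in by_prox) {
    g <- g[order(g$e_dist), ]
    expect_true(all(diff(g$uninduced) >= -1e-12))
  }
  # stronger core (lower energy) never lowers expression
  cores <- vapply(
    c(-4, -2, 0, 2),
    function(ec) {
      expression_grid(base, e_prox = 0, e_dist = 0, e_core = ec)$uninduced
    },
    numeric(1)
  )
  expect_true(all(diff(cores) <= 1e-12))

  # operator-free corner of the landscape has FC = 1
  corner <- expression_grid(base, e_prox = 50, e_dist = 50, e_core = -2)
  expect_equal(corner$fold_change, 1, tolerance = 1e-6)
})
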