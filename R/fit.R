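# Inference: fit the thermodynamic parameters to a processed expression
# table by multistart bounded nonlinear least squares on log10 expression.
# Core (-35,-10) energies are fitted per pair (the -10 and -35 energies enter
# every state only as a sum, so additive per-element energies are not
# separately identifiable); scrambled-operator energies are pinned
# non-binding, anchoring the expression scale together with r_max/r_min.

#' Fitting configuration
#'
#' @param train_fraction Fraction of variants used for fitting, in (0, 1];
#'   the complement is held out for evaluation.
#' @param seed Integer seed controlling the train split and the multistart
#'   draws.
#' @param n_starts Number of multistart initialisations (default 10); each
#'   start is explored briefly and the best is polished to convergence.
#' @param bounds Length-2 energy bounds in kT (default `c(-8, 8)`), applied
#'   to every binding and looping energy.
#' @param delta_max Upper bound for the IPTG penalty (kT).
#' @param tolerance Relative objective convergence tolerance.
#' @param floor_epsilon Floor applied to non-positive observed expression
#'   before taking log10; `NULL` (default) uses half the smallest positive
#'   observed value.
#' @param fit_delta Fit the IPTG penalty (needs both conditions); if `FALSE`
#'   `delta_iptg` is fixed at `delta_fixed`.
#' @param delta_fixed Value used when `fit_delta = FALSE`.
#' @param explore_maxit,polish_maxit L-BFGS-B iteration budgets for the
#'   exploration and polish stages.
#' @return A `fit_config` list.
#' @export
fit_config <- function(train_fraction = 1, seed = 1, n_starts = 10,
                       bounds = c(-8, 8), delta_max = 10, tolerance = 1e-14,
                       floor_epsilon = NULL, fit_delta = TRUE,
                       delta_fixed = 0, explore_maxit = 60,
                       polish_maxit = 1000) {
  stopifnot(
    train_fraction > 0, train_fraction <= 1, n_starts >= 1,
    length(bounds) == 2L, bounds[1] < bounds[2], is.finite(bounds)
  )
  structure(
    list(
      train_fraction = train_fraction, seed = as.integer(seed),
      n_starts = as.integer(n_starts), bounds = bounds,
      delta_max = delta_max, tolerance = tolerance,
      floor_epsilon = floor_epsilon, fit_delta = fit_delta,
      delta_fixed = delta_fixed, explore_maxit = explore_maxit,
      polish_maxit = polish_maxit
    ),
    class = "fit_config"
  )
}

# prepare the observation table: join expression with designs, floor
# non-positive values, build integer index vectors into the parameter vector
build_fit_data <- function(expr, designs, config) {
  needed <- c("variant_id", "condition", "expression")
  miss <- setdiff(needed, names(expr))
  if (length(miss) > 0L) {
    abort(paste0("expression table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  unknown <- setdiff(unique(expr$variant_id), designs$variant_id)
  if (length(unknown) > 0L) {
    abort(sprintf("%d variant(s) in the expression table are absent from the designs", length(unknown)))
  }
  design_cols <- c("variant_id", "proximal_op", "distal_op", "distalplus_op", "minus35", "minus10")
  obs <- dplyr::inner_join(
    expr[needed], designs[intersect(design_cols, names(designs))],
    by = "variant_id"
  )
  eps <- config$floor_epsilon %||% (min(obs$expression[obs$expression > 0]) / 2)
  obs$expression <- pmax(obs$expression, eps)
  obs$induced <- obs$condition == "induced"
  obs$core_pair <- paste0(obs$minus35, ":", obs$minus10)
  if (!"distalplus_op" %in% names(obs)) obs$distalplus_op <- NA_character_

  core_levels <- sort(unique(obs$core_pair))
  op_levels <- sort(unique(stats::na.omit(c(obs$proximal_op, obs$distal_op, obs$distalplus_op))))
  scram <- grepl("scram", op_levels, ignore.case = TRUE)
  free_ops <- op_levels[!scram]

  op_index <- function(x, free) {
    i <- match(x, free)
    i[is.na(x)] <- NA_integer_ # absent slot or scrambled: weight 0
    i
  }
  list(
    obs = obs,
    y = log10(obs$expression),
    core_idx = match(obs$core_pair, core_levels),
    prox_idx = op_index(obs$proximal_op, free_ops),
    dist_idx = op_index(obs$distal_op, free_ops),
    distplus_idx = op_index(obs$distalplus_op, free_ops),
    three = any(!is.na(obs$distalplus_op)),
    core_levels = core_levels, free_ops = free_ops,
    scram_ops = op_levels[scram],
    eps = eps
  )
}

# data-informed initial guess, refined by the optimiser: core energies are
# backed out of the repressor-free (scrambled-operator) variants through the
# two-state closed form, proximal operator energies from the median
# uninduced repression ratio against the scrambled proximal site, distal
# energies reuse the proximal guess of the same operator
smart_start <- function(fd, config) {
  obs <- fd$obs
  nc <- length(fd$core_levels)
  np <- length(fd$free_ops)
  unind <- !obs$induced
  scram_free <- is.na(fd$prox_idx) & is.na(fd$dist_idx) & is.na(fd$distplus_idx)
  rmin0 <- max(unname(quantile(obs$expression, 0.02)), 1e-3)
  rmax0 <- max(obs$expression)
  core0 <- vapply(seq_len(nc), function(k) {
    e <- obs$expression[unind & scram_free & fd$core_idx == k]
    if (length(e) == 0L) return(0)
    e <- median(e)
    wc <- (e - rmin0) / max(rmax0 - e, rmax0 * 1e-3)
    min(max(-log(max(wc, 1e-4)), config$bounds[1]), config$bounds[2])
  }, numeric(1))
  ref <- if (any(unind & scram_free)) {
    stats::aggregate(
      obs$expression[unind & scram_free],
      list(core = fd$core_idx[unind & scram_free]), median
    )
  } else {
    data.frame(core = integer(0), x = numeric(0))
  }
  prox0 <- vapply(seq_len(np), function(k) {
    sel <- unind & !is.na(fd$prox_idx) & fd$prox_idx == k & is.na(fd$dist_idx) &
      is.na(fd$distplus_idx)
    if (!any(sel) || nrow(ref) == 0L) return(0)
    e_ref <- setNames(ref$x, ref$core)[as.character(fd$core_idx[sel])]
    ratio <- median(e_ref / pmax(obs$expression[sel], 1e-6), na.rm = TRUE)
    if (!is.finite(ratio)) return(0)
    wp <- max(ratio - 1, 1e-3)
    min(max(-log(wp), config$bounds[1]), config$bounds[2])
  }, numeric(1))
  c(
    core0, prox0, prox0, -2.5, if (config$fit_delta) 3,
    log(rmin0), log(max(rmax0 - rmin0, 1e-2))
  )
}

# parameter vector layout: [core | prox | dist | e_loop | delta | log r_min |
# log (r_max - r_min)]
unpack_theta <- function(theta, fd, config) {
  nc <- length(fd$core_levels)
  np <- length(fd$free_ops)
  list(
    core = theta[seq_len(nc)],
    prox = theta[nc + seq_len(np)],
    dist = theta[nc + np + seq_len(np)],
    e_loop = theta[nc + 2 * np + 1],
    delta = if (config$fit_delta) theta[nc + 2 * np + 2] else config$delta_fixed,
    lrmin = theta[length(theta) - 1],
    lgap = theta[length(theta)]
  )
}

predict_log10 <- function(theta, fd, config) {
  p <- unpack_theta(theta, fd, config)
  at <- function(values, idx) {
    out <- values[idx]
    out[is.na(idx)] <- Inf
    out
  }
  shift <- fd$obs$induced * p$delta
  wc <- exp(-at(p$core, fd$core_idx))
  wp <- exp(-(at(p$prox, fd$prox_idx) + shift))
  wd <- exp(-(at(p$dist, fd$dist_idx) + shift))
  wl <- exp(-p$e_loop)
  if (fd$three) {
    wq <- exp(-(at(p$dist, fd$distplus_idx) + shift))
    z <- partition_three(wc, wp, wd, wq, wl)
  } else {
    z <- partition_two(wc, wp, wd, wl)
  }
  r_min <- exp(p$lrmin)
  r_max <- r_min + exp(p$lgap)
  log10(r_min + (r_max - r_min) * z$Z_active / z$Z)
}

#' Fit thermodynamic parameters to an expression table
#'
#' Minimises the sum of squared log10 residuals between model-predicted and
#' observed expression over all free binding energies, the looping energy,
#' the IPTG penalty (when both conditions are present) and the two rates.
#' Optimisation is bounded L-BFGS-B from `n_starts` seeded Latin-hypercube
#' initialisations; each start is explored briefly and the best is polished
#' to convergence, so the result is deterministic under the config seed.
#'
#' @param expr Expression tibble with columns `variant_id`, `condition`
#'   (`"uninduced"`/`"induced"`) and `expression` — typically the
#'   replicate-averaged output of [process_counts()].
#' @param designs Library manifest from [enumerate_library()] covering every
#'   variant in `expr`.
#' @param config A [fit_config()].
#' @return A `promoter_fit` object: fitted [thermo_params()], per-variant
#'   predictions and residuals, train/test ids, `r2_log10` on the fitted
#'   variants (`test_r2_log10` on the held-out set when `train_fraction < 1`),
#'   the monotone best-objective trace and the seed.
#' @seealso [cross_validate()], [predict_unseen_architecture()], [tidy()],
#'   [glance()]
#' @export
fit_parameters <- function(expr, designs, config = fit_config()) {
  if (!any(expr$condition == "induced") && config$fit_delta) {
    config$fit_delta <- FALSE
  }
  variant_ids <- unique(expr$variant_id)
  train_ids <- variant_ids
  if (config$train_fraction < 1) {
    n_train <- max(1L, round(config$train_fraction * length(variant_ids)))
    train_ids <- withr_seed(config$seed, sample(variant_ids, n_train))
  }
  test_ids <- setdiff(variant_ids, train_ids)

  fd_all <- build_fit_data(expr, designs, config)
  fd <- build_fit_data(expr[expr$variant_id %in% train_ids, ], designs, config)

  nc <- length(fd$core_levels)
  np <- length(fd$free_ops)
  n_free <- nc + 2 * np + 1 + as.integer(config$fit_delta) + 2
  if (nrow(fd$obs) < n_free) {
    abort(sprintf(
      "only %d observations for %d free parameters", nrow(fd$obs), n_free
    ))
  }

  trace_env <- new.env(parent = emptyenv())
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  objective <- function(theta) {
    val <- sum((predict_log10(theta, fd, config) - fd$y)^2)
    if (!is.finite(val)) val <- .Machine$double.xmax
    if (val < trace_env$best) {
      trace_env$best <- val
      trace_env$trace <- c(trace_env$trace, val)
    }
    val
  }

  lo_e <- config$bounds[1]
  hi_e <- config$bounds[2]
  lower <- c(rep(lo_e, nc + 2 * np + 1), if (config$fit_delta) 0, log(1e-4), log(1e-3))
  upper <- c(rep(hi_e, nc + 2 * np + 1), if (config$fit_delta) config$delta_max, log(1e3), log(1e6))

  smart <- smart_start(fd, config)
  starts <- withr_seed(config$seed + 1L, {
    u <- if (requireNamespace("lhs", quietly = TRUE)) {
      lhs::randomLHS(config$n_starts, length(lower))
    } else {
      matrix(runif(config$n_starts * length(lower)), nrow = config$n_starts)
    }
    s <- t(apply(u, 1, function(row) lower + row * (upper - lower)))
    # keep random energy starts in a moderate range and anchor the rates
    s[, seq_len(nc + 2 * np + 1)] <- pmax(pmin(s[, seq_len(nc + 2 * np + 1)], 3), -5)
    s[, ncol(s) - 1] <- smart[length(smart) - 1] + runif(config$n_starts, -0.5, 0.5)
    s[, ncol(s)] <- smart[length(smart)] + runif(config$n_starts, -0.5, 0.5)
    if (config$fit_delta) s[, nc + 2 * np + 2] <- runif(config$n_starts, 1, 5)
    # first start: the data-informed initial guess; second: a jitter of it
    s[1, ] <- smart
    if (config$n_starts >= 2) {
      s[2, ] <- pmin(pmax(smart + runif(length(smart), -0.5, 0.5), lower), upper)
    }
    s
  })

  explored <- purrr::map(seq_len(config$n_starts), function(i) {
    optim(
      starts[i, ], objective, method = "L-BFGS-B",
      lower = lower, upper = upper,
      control = list(maxit = config$explore_maxit, factr = 1e10)
    )
  })
  best <- explored[[which.min(purrr::map_dbl(explored, "value"))]]
  polished <- optim(
    best$par, objective, method = "L-BFGS-B",
    lower = lower, upper = upper,
    control = list(
      maxit = config$polish_maxit,
      factr = max(config$tolerance / .Machine$double.eps, 1),
      pgtol = 1e-10
    )
  )

  p <- unpack_theta(polished$par, fd, config)
  all_ops <- c(fd$free_ops, fd$scram_ops)
  params <- thermo_params(
    e_core = setNames(p$core, fd$core_levels),
    e_prox = setNames(c(p$prox, rep(Inf, length(fd$scram_ops))), all_ops),
    e_dist = setNames(c(p$dist, rep(Inf, length(fd$scram_ops))), all_ops),
    e_loop = p$e_loop, delta_iptg = max(p$delta, 0),
    r_min = exp(p$lrmin), r_max = exp(p$lrmin) + exp(p$lgap)
  )

  pred_all <- predict_log10(polished$par, fd_all, config)
  residuals <- tibble::tibble(
    variant_id = fd_all$obs$variant_id,
    condition = fd_all$obs$condition,
    observed = fd_all$obs$expression,
    predicted = 10^pred_all,
    residual_log10 = log10(fd_all$obs$expression) - pred_all,
    split = ifelse(fd_all$obs$variant_id %in% train_ids, "train", "test")
  )
  train_res <- residuals[residuals$split == "train", ]
  test_res <- residuals[residuals$split == "test", ]

  structure(
    list(
      params = params,
      r2_log10 = goodness_of_fit(train_res$observed, train_res$predicted),
      test_r2_log10 = if (nrow(test_res) > 0L) {
        goodness_of_fit(test_res$observed, test_res$predicted)
      } else {
        NA_real_
      },
      residuals = residuals,
      train_ids = train_ids, test_ids = test_ids,
      objective = polished$value,
      trace = trace_env$trace,
      n_obs = nrow(fd$obs), n_free = n_free,
      floor_epsilon = fd$eps,
      seed = config$seed, config = config
    ),
    class = "promoter_fit"
  )
}

#' Coefficient of determination on log10 expression
#'
#' `1 - SS_res / SS_tot` computed on log10-transformed values, which damps
#' the influence of large expression outliers.
#'
#' @param observed,predicted Positive numeric vectors of equal length.
#' @return The r-squared on the log10 scale.
#' @examples
#' goodness_of_fit(c(1, 10, 100), c(1, 10, 100)) # 1
#' goodness_of_fit(c(1, 10, 100), c(1, 100, 10)) # 0
#' @export
goodness_of_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (any(observed <= 0) || any(predicted <= 0)) {
    abort("goodness_of_fit needs positive expression values")
  }
  lo <- log10(observed)
  lp <- log10(predicted)
  ss_tot <- sum((lo - mean(lo))^2)
  if (ss_tot == 0) abort("observed expression has zero variance on the log10 scale")
  1 - sum((lo - lp)^2) / ss_tot
}

#' Cross-validated fit
#'
#' Fits on a seeded random fraction of the variants and reports the
#' goodness of fit on the held-out complement only.
#'
#' @inheritParams fit_parameters
#' @return A `promoter_fit` whose `r2_log10` is the held-out r-squared
#'   (the in-sample value is kept as `train_r2_log10`).
#' @export
cross_validate <- function(expr, designs, config) {
  if (config$train_fraction >= 1) {
    abort("cross_validate needs train_fraction < 1")
  }
  fit <- fit_parameters(expr, designs, config)
  fit$train_r2_log10 <- fit$r2_log10
  fit$r2_log10 <- fit$test_r2_log10
  fit
}

#' Zero-shot prediction of an unseen architecture
#'
#' Predicts expression for a three-operator manifest from parameters fitted
#' on two-operator data. Distal+ slots reuse the fitted distal-position
#' energy of the same operator sequence; no parameter is refitted.
#'
#' @param fit A `promoter_fit` (or bare [thermo_params()]).
#' @param designs Manifest of the unseen architecture.
#' @param observed Optional expression tibble (`variant_id`, `condition`,
#'   `expression`) to score against.
#' @return A list with `predictions` (manifest + predicted expression per
#'   condition) and, when `observed` is given, `r2_log10`.
#' @export
predict_unseen_architecture <- function(fit, designs, observed = NULL) {
  params <- if (inherits(fit, "promoter_fit")) fit$params else fit
  ops <- unique(stats::na.omit(c(
    designs$proximal_op, designs$distal_op, designs$distalplus_op
  )))
  missing_ops <- setdiff(ops, names(params$e_prox))
  if (length(missing_ops) > 0L) {
    abort(paste0(
      "fitted parameters are missing operator(s): ",
      paste(missing_ops, collapse = ", ")
    ))
  }
  preds <- dplyr::bind_rows(
    predict_expression(designs, params, induced = FALSE),
    predict_expression(designs, params, induced = TRUE)
  )[, c("variant_id", "architecture", "condition", "expression")]
  names(preds)[names(preds) == "expression"] <- "predicted"
  out <- list(predictions = preds)
  if (!is.null(observed)) {
    joined <- dplyr::inner_join(
      preds, observed[, c("variant_id", "condition", "expression")],
      by = c("variant_id", "condition")
    )
    eps <- min(joined$expression[joined$expression > 0]) / 2
    out$r2_log10 <- goodness_of_fit(pmax(joined$expression, eps), joined$predicted)
    out$scored <- joined
  }
  out
}

#' Compare fitted energies with a known ground truth
#'
#' Pairs every finite fitted binding/looping/IPTG energy with its
#' ground-truth value and reports the root-mean-square error, the headline
#' statistic of parameter-recovery simulations.
#'
#' @param fit A `promoter_fit` or [thermo_params()].
#' @param truth The ground-truth [thermo_params()].
#' @return A list with `by_term` (tibble of family, term, true, estimate)
#'   and `rmse`.
#' @export
energy_recovery <- function(fit, truth) {
  est <- if (inherits(fit, "promoter_fit")) fit$params else fit
  pick <- function(family, est_v, true_v) {
    shared <- intersect(names(est_v), names(true_v))
    shared <- shared[is.finite(est_v[shared]) & is.finite(true_v[shared])]
    tibble::tibble(
      family = family, term = shared,
      true = unname(true_v[shared]), estimate = unname(est_v[shared])
    )
  }
  by_term <- dplyr::bind_rows(
    pick("core", est$e_core, truth$e_core),
    pick("proximal", est$e_prox, truth$e_prox),
    pick("distal", est$e_dist, truth$e_dist),
    tibble::tibble(
      family = c("loop", "iptg"), term = c("e_loop", "delta_iptg"),
      true = c(truth$e_loop, truth$delta_iptg),
      estimate = c(est$e_loop, est$delta_iptg)
    )
  )
  list(
    by_term = by_term,
    rmse = sqrt(mean((by_term$estimate - by_term$true)^2))
  )
}

#' @export
print.promoter_fit <- function(x, ...) {
  cat("<promoter_fit>\n")
  cat(sprintf(
    "  %d observations, %d free parameters, objective %.4g\n",
    x$n_obs, x$n_free, x$objective
  ))
  cat(sprintf("  r2 (log10): %.4f", x$r2_log10))
  if (!is.na(x$test_r2_log10)) cat(sprintf("  held-out r2: %.4f", x$test_r2_log10))
  cat("\n")
  invisible(x)
}

#' Tidy a fitted promoter model
#'
#' @param x A `promoter_fit`.
#' @param ... Unused.
#' @return One row per fitted parameter with `family` (`core`, `proximal`,
#'   `distal`, `loop`, `iptg`, `rate`), `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.promoter_fit <- function(x, ...) {
  p <- x$params
  dplyr::bind_rows(
    tibble::tibble(family = "core", term = names(p$e_core), estimate = unname(p$e_core)),
    tibble::tibble(family = "proximal", term = names(p$e_prox), estimate = unname(p$e_prox)),
    tibble::tibble(family = "distal", term = names(p$e_dist), estimate = unname(p$e_dist)),
    tibble::tibble(
      family = c("loop", "iptg", "rate", "rate"),
      term = c("e_loop", "delta_iptg", "r_max", "r_min"),
      estimate = c(p$e_loop, p$delta_iptg, p$r_max, p$r_min)
    )
  )
}

#' @rdname tidy.promoter_fit
#' @exportS3Method generics::glance
glance.promoter_fit <- function(x, ...) {
  tibble::tibble(
    r2_log10 = x$r2_log10, test_r2_log10 = x$test_r2_log10,
    objective = x$objective, n_obs = x$n_obs, n_free = x$n_free,
    n_train = length(x$train_ids), n_test = length(x$test_ids),
    seed = x$seed
  )
}

#' @rdname tidy.promoter_fit
#' @exportS3Method generics::augment
augment.promoter_fit <- function(x, ...) {
  x$residuals
}
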