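# Barcode-count processing: counts-per-million normalisation, the minimum
# barcode filter, RNA/DNA aggregation to per-variant expression, negative-
# control normalisation, replicate averaging, fold change and activity calls.
#
# A barcode count table has one row per (barcode, sample) with columns
# barcode, variant_id, condition ("uninduced"/"induced"), replicate, assay
# ("DNA"/"RNA") and count. A sample is one condition x replicate x assay
# combination.

sample_cols <- c("condition", "replicate", "assay")

check_count_table <- function(counts) {
  required <- c("barcode", "variant_id", sample_cols, "count")
  miss <- setdiff(required, names(counts))
  if (length(miss) > 0L) {
    abort(paste0("count table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(counts$count < 0)) abort("counts must be non-negative")
  dup <- counts |>
    dplyr::count(.data$barcode, .data$condition, .data$replicate, .data$assay) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) abort("duplicate (barcode, sample) rows in count table")
  multi <- counts |>
    dplyr::distinct(.data$barcode, .data$variant_id) |>
    dplyr::count(.data$barcode) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    abort(sprintf("%d barcode(s) map to more than one variant", nrow(multi)))
  }
  invisible(counts)
}

#' Normalise barcode counts to counts per million
#'
#' Per sample, `normalized = count / total sample reads * 1e6`, making
#' samples of different sequencing depth comparable.
#'
#' @param counts A barcode count tibble (see package overview); columns
#'   `barcode`, `variant_id`, `condition`, `replicate`, `assay`, `count`.
#' @return The table with an added `normalized` column.
#' @examples
#' counts <- tibble::tibble(
#'   barcode = "b1", variant_id = "v", condition = "uninduced",
#'   replicate = 1, assay = "DNA", count = 250
#' )
#' # with a 5e6-read sample the normalized count would be 50
#' @export
normalize_counts <- function(counts) {
  check_count_table(counts)
  out <- counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(sample_cols))) |>
    dplyr::mutate(.total = sum(.data$count)) |>
    dplyr::ungroup()
  if (any(out$.total == 0)) abort("a sample has zero total reads")
  out$normalized <- out$count / out$.total * 1e6
  out$.total <- NULL
  out
}

#' Drop variants with too few barcodes in any sample
#'
#' A variant is kept only if it has at least `k` distinct observed barcodes
#' (count > 0) in every sample present in the table. The filter is
#' idempotent.
#'
#' @param counts Barcode count tibble.
#' @param k Minimum number of barcodes per sample (default 3).
#' @return The filtered table.
#' @export
filter_min_barcodes <- function(counts, k = 3) {
  check_count_table(counts)
  n_samples <- nrow(dplyr::distinct(counts, dplyr::across(dplyr::all_of(sample_cols))))
  keep <- counts |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$variant_id, dplyr::across(dplyr::all_of(sample_cols))) |>
    dplyr::summarise(n_bc = dplyr::n_distinct(.data$barcode), .groups = "drop") |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(
      ok = dplyr::n() == n_samples && all(.data$n_bc >= k),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$ok)
  dplyr::semi_join(counts, keep, by = "variant_id")
}

#' Aggregate barcode counts to per-variant expression
#'
#' Per variant and sample pair, expression is the ratio of summed normalised
#' RNA counts to summed normalised DNA counts over all the variant's
#' barcodes.
#'
#' @param counts Barcode count tibble with a `normalized` column (from
#'   [normalize_counts()]), typically already filtered with
#'   [filter_min_barcodes()].
#' @return An expression tibble with one row per variant x condition x
#'   replicate: `variant_id`, `condition`, `replicate`, `expression`,
#'   `n_barcodes`. Variants whose DNA sum is zero in a sample are dropped
#'   with a warning.
#' @export
aggregate_expression <- function(counts) {
  if (!"normalized" %in% names(counts)) {
    abort("counts must be normalised first (see normalize_counts())")
  }
  wide <- counts |>
    dplyr::group_by(
      .data$variant_id, .data$condition, .data$replicate, .data$assay
    ) |>
    dplyr::summarise(
      total = sum(.data$normalized),
      n_barcodes = dplyr::n_distinct(.data$barcode[.data$count > 0]),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "assay", values_from = c("total", "n_barcodes")
    )
  bad <- wide$total_DNA <= 0 | is.na(wide$total_DNA) | is.na(wide$total_RNA)
  if (any(bad)) {
    warn(sprintf(
      "dropping %d variant x sample combinations with zero DNA",
      sum(bad)
    ))
    wide <- wide[!bad, ]
  }
  tibble::tibble(
    variant_id = wide$variant_id,
    condition = wide$condition,
    replicate = wide$replicate,
    expression = wide$total_RNA / wide$total_DNA,
    n_barcodes = pmin(wide$n_barcodes_DNA, wide$n_barcodes_RNA, na.rm = TRUE)
  )
}

#' Normalise expression to negative controls
#'
#' Divides every expression value by the median expression of the negative-
#' control variants within the same condition x replicate, putting all
#' replicates on a common scale anchored at the background. If no control
#' list is given, variants carrying the scrambled operator in every operator
#' slot are used.
#'
#' @param expr Expression tibble from [aggregate_expression()].
#' @param negative_control_ids Character vector of control `variant_id`s.
#' @return The table with `expression` rescaled and a `normalized` flag set.
#' @export
normalize_to_controls <- function(expr, negative_control_ids = NULL) {
  if (is.null(negative_control_ids)) {
    negative_control_ids <- unique(
      expr$variant_id[grepl("O_scram.*O_scram|control", expr$variant_id)]
    )
  }
  if (length(negative_control_ids) == 0L) {
    abort("no negative-control variants supplied or detected")
  }
  out <- expr |>
    dplyr::group_by(.data$condition, .data$replicate) |>
    dplyr::mutate(
      .ctrl = median(.data$expression[.data$variant_id %in% negative_control_ids])
    ) |>
    dplyr::ungroup()
  if (any(is.na(out$.ctrl) | out$.ctrl <= 0)) {
    abort("a replicate has no surviving (positive) negative controls")
  }
  out$expression <- out$expression / out$.ctrl
  out$.ctrl <- NULL
  out$normalized <- TRUE
  out
}

#' Average expression across biological replicates
#'
#' @param expr Expression tibble (per replicate).
#' @return One row per variant x condition with the arithmetic mean
#'   expression (`replicate = "mean"`), the barcode count being the minimum
#'   across replicates.
#' @export
average_replicates <- function(expr) {
  expr |>
    dplyr::group_by(.data$variant_id, .data$condition) |>
    dplyr::summarise(
      expression = mean(.data$expression),
      n_barcodes = min(.data$n_barcodes),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(replicate = "mean")
}

#' Induction fold change per variant
#'
#' Fold change is induced / uninduced expression (both already control-
#' normalised). Variants missing either condition get `NA` with a flag, not
#' zero.
#'
#' @param expr Replicate-averaged expression tibble (from
#'   [average_replicates()]).
#' @return One row per variant: `variant_id`, `uninduced`, `induced`,
#'   `fold_change`, `fc_defined`.
#' @export
compute_fold_change <- function(expr) {
  wide <- expr |>
    dplyr::select("variant_id", "condition", "expression") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "expression")
  for (col in c("uninduced", "induced")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  wide$fc_defined <- !is.na(wide$uninduced) & !is.na(wide$induced) & wide$uninduced > 0
  wide$fold_change <- ifelse(wide$fc_defined, wide$induced / wide$uninduced, NA_real_)
  wide
}

#' Call transcriptionally active variants
#'
#' A variant is active when its expression exceeds the median of the
#' negative controls plus twice their median absolute deviation (MAD without
#' a consistency constant), the threshold separating signal from background.
#' The comparison is strict: expression exactly at the threshold is inactive.
#'
#' @param expr Expression tibble (any granularity with an `expression`
#'   column).
#' @param negative_control_ids Character vector of control `variant_id`s.
#' @return The table with added `active_threshold` and `active` columns.
#' @export
classify_active <- function(expr, negative_control_ids) {
  ctrl <- expr$expression[expr$variant_id %in% negative_control_ids]
  if (length(ctrl) == 0L) abort("no negative controls present")
  if (length(ctrl) < 3L) {
    warn("fewer than 3 negative controls: activity threshold is unreliable")
  }
  threshold <- median(ctrl) + 2 * median(abs(ctrl - median(ctrl)))
  out <- expr
  out$active_threshold <- threshold
  out$active <- out$expression > threshold
  out
}

#' Correlation of expression between replicates
#'
#' Pearson correlation between two biological replicates, computed on log10
#' expression by default because expression spans orders of magnitude.
#'
#' @param expr Per-replicate expression tibble.
#' @param replicates Length-2 vector naming the replicates to compare
#'   (default: the first two present).
#' @param log10_scale Correlate log10 values (default `TRUE`)?
#' @return A tibble with one row per condition: `condition`, `r`,
#'   `n_variants`.
#' @export
replicate_correlation <- function(expr, replicates = NULL, log10_scale = TRUE) {
  reps <- replicates %||% head(sort(unique(expr$replicate)), 2L)
  if (length(reps) != 2L) abort("need exactly two replicates to correlate")
  wide <- expr |>
    dplyr::filter(.data$replicate %in% reps) |>
    dplyr::select("variant_id", "condition", "replicate", "expression") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "expression") |>
    tidyr::drop_na()
  wide |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      r = {
        x <- .data[[as.character(reps[1])]]
        y <- .data[[as.character(reps[2])]]
        if (dplyr::n() < 3L) abort("replicates share fewer than 3 variants")
        if (log10_scale) cor(log10(x), log10(y)) else cor(x, y)
      },
      n_variants = dplyr::n(),
      .groups = "drop"
    )
}

#' Run the whole count-processing pipeline
#'
#' Convenience wrapper chaining [normalize_counts()],
#' [filter_min_barcodes()], [aggregate_expression()],
#' [normalize_to_controls()], [average_replicates()] and
#' [compute_fold_change()].
#'
#' @param counts Barcode count tibble.
#' @param negative_control_ids Control variant ids (passed through).
#' @param min_barcodes Minimum barcodes per sample (default 3).
#' @return A list with `per_replicate` (control-normalised expression per
#'   replicate), `expression` (replicate-averaged) and `fold_change` tibbles.
#' @export
process_counts <- function(counts, negative_control_ids = NULL, min_barcodes = 3) {
  per_rep <- counts |>
    normalize_counts() |>
    filter_min_barcodes(k = min_barcodes) |>
    aggregate_expression() |>
    normalize_to_controls(negative_control_ids)
  averaged <- average_replicates(per_rep)
  list(
    per_replicate = per_rep,
    expression = averaged,
    fold_change = compute_fold_change(averaged)
  )
}
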