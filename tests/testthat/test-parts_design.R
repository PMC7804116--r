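test_that("catalog loading validates structure, alphabet and uniqueness", {
  catalog <- default_catalog()
  expect_s3_class(catalog, "tbl_df")
  expect_true(all(c("name", "role", "sequence", "source") %in% names(catalog)))

  write_cat <- function(df) {
    path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
    readr::write_tsv(df, path)
    path
  }

  # a catalog with 10 proximal, 10 distal, 4 -10, 4 -35 rows holds 28 parts
  ops <- paste0("Op", 1:10)
  small <- dplyr::bind_rows(
    tibble::tibble(name = ops, role = "proximal_op", sequence = strrep("ACGTA", 5), source = "x"),
    tibble::tibble(name = ops, role = "distal_op", sequence = strrep("ACGTA", 5), source = "x"),
    tibble::tibble(name = paste0("m10_", 1:4), role = "minus10", sequence = "TATAAT", source = "x"),
    tibble::tibble(name = paste0("m35_", 1:4), role = "minus35", sequence = "TTGACA", source = "x")
  )
  expect_equal(nrow(load_catalog(write_cat(small))), 28L)

  bad_alpha <- small
  bad_alpha$sequence[1] <- "ATGN"
  expect_error(load_catalog(write_cat(bad_alpha)), "N")

  dup <- dplyr::bind_rows(small, small[1, ])
  expect_error(load_catalog(write_cat(dup)), "duplicate")

  no_role <- small[, c("name", "sequence", "source")]
  expect_error(load_catalog(write_cat(no_role)), "role")
})

test_that("operator scrambling preserves composition and is reproducible", {
  o1 <- "AATTGTGAGCGGATAACAATT"
  s1 <- scramble_operator(o1, seed = 11)
  expect_equal(nchar(s1), nchar(o1))
  count_bases <- function(s) table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  expect_equal(count_bases(s1), count_bases(o1))
  expect_identical(scramble_operator(o1, seed = 11), s1)
  expect_equal(
    mean(strsplit(s1, "")[[1]] %in% c("G", "C")),
    mean(strsplit(o1, "")[[1]] %in% c("G", "C"))
  )
  # 4-mer keeps its exact composition whatever the seed
  for (seed in 1:5) {
    expect_equal(count_bases(scramble_operator("AATT", seed)), count_bases("AATT"))
  }
})

test_that("assembly places parts at the architecture's declared intervals", {
  catalog <- default_catalog()

  seq_pc <- assemble_sequence("pcombo", parts = c(
    proximal_op = "O_1", distal_op = "O_sym",
    minus10 = "TATAAT", minus35 = "TTGACA"
  ))
  spans <- attr(seq_pc, "spans")
  prox <- spans[spans$role == "proximal_op", ]
  # 21 bp operator centred at +11 spans +1..+21
  expect_equal(c(prox$start, prox$end), c(1L, 21L))
  # the assembled string carries the part at that interval (window -100..+21)
  expect_equal(
    substr(as.character(seq_pc), 101, 121),
    catalog_part(catalog, "O_1", "proximal_op")
  )
  expect_equal(
    spans[spans$role == "minus10", c("start", "end")],
    tibble::tibble(start = -12L, end = -7L),
    ignore_attr = TRUE
  )

  # 23 bp spacing-library operator centred at +12 spans +1..+23
  seq_sp <- assemble_sequence(
    "spacing",
    parts = c(proximal_op = "LacI_prox", distal_op = "LacI_dist"),
    placement = list(distal_op = -90)
  )
  sp <- attr(seq_sp, "spans")
  expect_equal(
    unlist(sp[sp$role == "proximal_op", c("start", "end")], use.names = FALSE),
    c(1L, 23L)
  )

  # the 17 bp spacer operator exactly fills the gap between the hexamers
  seq_ps <- assemble_sequence(
    "pspacer",
    parts = c(
      distal_op = "O_1", minus35 = "TTGACA", minus10 = "TATAAT",
      spacer_op = "O_sym"
    ),
    placement = list(interoperator_distance = 55)
  )
  ps <- attr(seq_ps, "spans")
  expect_equal(
    unlist(ps[ps$role == "spacer_op", c("start", "end")], use.names = FALSE),
    c(-29L, -13L)
  )
  expect_equal(ps$end[ps$role == "minus35"], -30L)
  expect_equal(ps$start[ps$role == "minus10"], -12L)

  # determinism: identical inputs give identical output
  expect_identical(
    as.character(seq_pc),
    as.character(assemble_sequence("pcombo", parts = c(
      proximal_op = "O_1", distal_op = "O_sym",
      minus10 = "TATAAT", minus35 = "TTGACA"
    )))
  )

  # overlapping placements are rejected with both slot names
  expect_error(
    assemble_sequence(
      "spacing",
      parts = c(proximal_op = "LacI_prox", distal_op = "LacI_dist"),
      placement = list(distal_op = -1)
    ),
    "proximal_op.*distal_op|distal_op.*proximal_op"
  )
})

test_that("library enumeration reproduces every printed design size", {
  sizes <- c(
    spacing = 624L, pcombo = 1600L, pmultiple = 2000L,
    pspacer = 4400L, psteric = 1600L
  )
  for (lib in names(sizes)) {
    manifest <- enumerate_library(lib, assemble = FALSE)
    expect_equal(nrow(manifest), sizes[[lib]], label = lib)
    expect_false(anyDuplicated(manifest$variant_id) > 0, label = lib)
  }
})

test_that("enumeration details follow the designs", {
  spacing <- enumerate_library("spacing", assemble = FALSE)
  # the distal series covers exactly -83..-116
  centers <- sort(unique(spacing$distal_center[!is.na(spacing$distal_center) &
    spacing$config != "both_scrambled"]))
  expect_equal(centers, sort(-(83:116)))
  expect_equal(length(unique(spacing$tf)), 6L)

  pcombo <- enumerate_library("pcombo", assemble = FALSE)
  expect_equal(length(unique(pcombo$proximal_op)), 10L)
  expect_equal(length(unique(pcombo$distal_op)), 10L)
  # determinism of ids across calls
  expect_identical(pcombo$variant_id, enumerate_library("pcombo", assemble = FALSE)$variant_id)

  pspacer <- enumerate_library("pspacer", assemble = FALSE)
  expect_equal(sort(unique(pspacer$interoperator_distance)), 46:56)

  # a catalog missing a referenced part is rejected
  pruned <- default_catalog() |> dplyr::filter(.data$name != "O_sym")
  expect_error(enumerate_library("pcombo", catalog = pruned), "O_sym")
})

test_that("the -10 element sits at one fixed position across a library", {
  manifest <- enumerate_library("pcombo") |> dplyr::slice_sample(n = 25)
  # window -100..+21: position -12 is string index 89
  catalog <- default_catalog()
  m10 <- vapply(
    seq_len(nrow(manifest)),
    function(i) substr(manifest$sequence[i], 89, 94),
    character(1)
  )
  expect_identical(
    m10,
    vapply(manifest$minus10, function(p) catalog_part(catalog, p, "minus10"), character(1), USE.NAMES = FALSE)
  )
})

test_that("manifests and FASTA round-trip through write_library", {
  dir <- withr::local_tempdir()
  manifest <- enumerate_library("pcombo") |> dplyr::slice_head(n = 5)
  paths <- write_library(manifest, dir)
  expect_true(all(file.exists(paths)))
  fasta <- readLines(file.path(dir, "variants.fasta"))
  expect_equal(sum(startsWith(fasta, ">")), 5L)
  expect_equal(sub(">", "", fasta[1]), manifest$variant_id[1])
})
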