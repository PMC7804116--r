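# Combinatorial enumeration of the five promoter libraries. Counts are fixed
# by the designs (spacing 624, pcombo 1600, pmultiple 2000, pspacer 4400,
# psteric 1600) and are independent of the catalog sequences.

TEN_OPERATORS <- c(
  "O_1", "O_2-var", "O_3", "O_sym", "O_scram",
  "O_1:R-sym", "O_2:L-sym", "O_2:R-sym", "O_3:L-sym", "O_3:R-sym"
)
FIVE_OPERATORS <- c("O_1", "O_2-var", "O_3", "O_sym", "O_scram")
SPACING_TFS <- c("LacI", "AraC", "GalR", "GlpR", "LldR", "PurR")
MINUS10_SET <- c("TATAAT", "TATGTT", "TACACT", "CATAAT")
MINUS35_SET <- c("TTGACA", "TTTACA", "TTGATT", "TCGACC")
UP_SET <- paste0("UP_", 1:4)
SPACING_DISTAL_CENTERS <- -(83:116)

#' Enumerate a promoter library
#'
#' Produces the full Cartesian design of one of the five libraries as a
#' manifest tibble: one row per variant with the part chosen for every slot,
#' the variable placements, and (optionally) the assembled sequence.
#' The design sizes are spacing 624, pcombo 1600, pmultiple 2000,
#' pspacer 4400 and psteric 1600.
#'
#' @param name Library name: `"spacing"`, `"pcombo"`, `"pmultiple"`,
#'   `"pspacer"` or `"psteric"`.
#' @param catalog Part catalog (defaults to the shipped catalog). The catalog
#'   must contain every part the design references.
#' @param assemble If `TRUE` (default), assemble and attach the variant
#'   sequences.
#' @return A tibble with columns `variant_id`, `architecture`, one column per
#'   slot role, the placement columns (`proximal_center`, `distal_center`,
#'   `interoperator_distance`, `config`, `tf`) and `sequence`.
#' @examples
#' pcombo <- enumerate_library("pcombo", assemble = FALSE)
#' nrow(pcombo) # 1600 = 10 proximal x 4 -35 x 4 -10 x 10 distal
#' @export
enumerate_library <- function(name, catalog = default_catalog(), assemble = TRUE) {
  name <- match.arg(name, c("spacing", "pcombo", "pmultiple", "pspacer", "psteric"))
  enum <- switch(name,
    spacing = enum_spacing(catalog),
    pcombo = enum_pcombo(),
    pmultiple = enum_pmultiple(),
    pspacer = enum_pspacer(),
    psteric = enum_psteric()
  )
  manifest <- enum$manifest
  catalog <- enum$catalog %||% catalog
  slot_cols <- c(
    "proximal_op", "distal_op", "distalplus_op", "spacer_op", "core_op",
    "minus35", "minus10", "up_element", "ext10"
  )
  for (col in slot_cols) {
    if (!col %in% names(manifest)) manifest[[col]] <- NA_character_
  }
  for (col in c("proximal_center", "distal_center", "interoperator_distance")) {
    if (!col %in% names(manifest)) manifest[[col]] <- NA_integer_
  }
  if (!"config" %in% names(manifest)) manifest$config <- NA_character_
  if (!"tf" %in% names(manifest)) manifest$tf <- NA_character_
  manifest <- manifest[, c(
    "variant_id", "architecture", "tf", slot_cols,
    "proximal_center", "distal_center", "interoperator_distance", "config"
  )]
  referenced <- unique(stats::na.omit(unlist(
    purrr::map(slot_cols, function(col) {
      parts <- unique(manifest[[col]])
      parts <- parts[!is.na(parts)]
      if (length(parts) == 0L) return(NULL)
      paste0(parts, "\r", col)
    })
  )))
  have <- paste0(catalog$name, "\r", catalog$role)
  missing_parts <- referenced[!referenced %in% have]
  if (length(missing_parts) > 0L) {
    abort(paste0(
      "catalog is missing referenced part(s): ",
      paste(gsub("\r", " as ", missing_parts), collapse = ", ")
    ))
  }
  if (anyDuplicated(manifest$variant_id)) abort("internal error: duplicate variant ids")
  if (assemble) {
    manifest$sequence <- assemble_manifest(manifest, catalog)
  }
  manifest
}

enum_pcombo <- function() {
  g <- tidyr::expand_grid(
    proximal_op = TEN_OPERATORS, minus35 = MINUS35_SET,
    minus10 = MINUS10_SET, distal_op = TEN_OPERATORS
  )
  g$architecture <- "pcombo"
  g$proximal_center <- 11L
  g$distal_center <- -90L
  g$variant_id <- paste0(
    "pcombo:", g$proximal_op, "+", g$minus35, "+", g$minus10, "+", g$distal_op,
    ":p11_d-90"
  )
  list(manifest = g)
}

enum_pmultiple <- function() {
  g <- tidyr::expand_grid(
    distalplus_op = FIVE_OPERATORS, distal_op = FIVE_OPERATORS,
    minus35 = MINUS35_SET, minus10 = MINUS10_SET, proximal_op = FIVE_OPERATORS
  )
  g$architecture <- "pmultiple"
  g$proximal_center <- 11L
  g$distal_center <- -90L
  g$variant_id <- paste0(
    "pmultiple:", g$distalplus_op, "+", g$distal_op, "+", g$minus35, "+",
    g$minus10, "+", g$proximal_op, ":p11_d-90_dp-111"
  )
  list(manifest = g)
}

enum_pspacer <- function() {
  g <- tidyr::expand_grid(
    distal_op = FIVE_OPERATORS, minus35 = MINUS35_SET, minus10 = MINUS10_SET,
    spacer_op = FIVE_OPERATORS, interoperator_distance = 46:56
  )
  g$architecture <- "pspacer"
  g$distal_center <- -(20L + g$interoperator_distance)
  g$variant_id <- paste0(
    "pspacer:", g$distal_op, "+", g$minus35, "+", g$minus10, "+", g$spacer_op,
    ":iod", g$interoperator_distance
  )
  list(manifest = g)
}

enum_psteric <- function() {
  g <- tidyr::expand_grid(
    minus10 = MINUS10_SET, core_op = FIVE_OPERATORS,
    proximal_op = FIVE_OPERATORS, up_element = UP_SET,
    ext10 = c("TGG", NA_character_), proximal_center = c(11L, 30L)
  )
  g$architecture <- "psteric"
  g$variant_id <- paste0(
    "psteric:", g$minus10, "+", g$core_op, "+", g$proximal_op, "+",
    g$up_element, ":p", g$proximal_center,
    ifelse(is.na(g$ext10), "_noext", "_ext10")
  )
  list(manifest = g)
}

enum_spacing <- function(catalog) {
  # scrambled companion sites are generated deterministically per TF
  scram_rows <- purrr::imap(SPACING_TFS, function(tf, i) {
    dplyr::bind_rows(
      scramble_operator(
        catalog[catalog$name == paste0(tf, "_prox") & catalog$role == "proximal_op", ],
        seed = 1000L + i
      ),
      scramble_operator(
        catalog[catalog$name == paste0(tf, "_dist") & catalog$role == "distal_op", ],
        seed = 2000L + i
      )
    )
  })
  catalog <- dplyr::bind_rows(catalog, dplyr::bind_rows(scram_rows))
  per_tf <- purrr::map(SPACING_TFS, function(tf) {
    prox <- paste0(tf, "_prox")
    dist <- paste0(tf, "_dist")
    series <- tidyr::expand_grid(
      distal_center = SPACING_DISTAL_CENTERS,
      config = c("intact", "prox_scrambled", "dist_scrambled")
    )
    series$proximal_op <- ifelse(series$config == "prox_scrambled", paste0(prox, "_scram"), prox)
    series$distal_op <- ifelse(series$config == "dist_scrambled", paste0(dist, "_scram"), dist)
    controls <- tibble::tibble(
      distal_center = c(NA_integer_, -90L),
      config = c("proximal_only", "both_scrambled"),
      proximal_op = c(prox, paste0(prox, "_scram")),
      distal_op = c(NA_character_, paste0(dist, "_scram"))
    )
    out <- dplyr::bind_rows(series, controls)
    out$tf <- tf
    out
  })
  g <- dplyr::bind_rows(per_tf)
  g$architecture <- "spacing"
  g$proximal_center <- 12L
  g$variant_id <- paste0(
    "spacing:", g$tf, ":",
    ifelse(is.na(g$distal_center), "", sprintf("d%d_", g$distal_center)),
    g$config
  )
  list(manifest = g, catalog = catalog)
}

# fast batched assembly: slot axis indices are resolved once per unique
# placement, then each variant is a handful of vector assignments
assemble_manifest <- function(manifest, catalog) {
  window_cache <- new.env(parent = emptyenv())
  part_chars <- new.env(parent = emptyenv())
  backbone_axis <- axis_positions(BACKBONE_WINDOW[1], BACKBONE_WINDOW[2])
  backbone <- strsplit(catalog_part(catalog, "lacUV5_backbone", "backbone"), "")[[1]]

  get_part <- function(name, role) {
    key <- paste0(role, "\r", name)
    if (is.null(part_chars[[key]])) {
      part_chars[[key]] <- strsplit(catalog_part(catalog, name, role), "")[[1]]
    }
    part_chars[[key]]
  }

  out <- character(nrow(manifest))
  for (arch_name in unique(manifest$architecture)) {
    arch <- architecture_spec(arch_name)
    rows <- which(manifest$architecture == arch_name)
    window <- axis_positions(arch$window[1], arch$window[2])
    base_chars <- backbone[match(window, backbone_axis)]
    idx_cache <- new.env(parent = emptyenv())
    slot_idx <- function(role, center_key) {
      key <- paste0(role, "\r", center_key)
      if (is.null(idx_cache[[key]])) {
        row <- arch$slots[arch$slots$role == role, ]
        placement <- if (row$type == "center_var") {
          setNames(list(as.integer(center_key)), role)
        } else {
          list()
        }
        idx_cache[[key]] <- match(slot_positions(row, placement), window)
      }
      idx_cache[[key]]
    }
    for (r in rows) {
      chars <- base_chars
      for (i in seq_len(nrow(arch$slots))) {
        role <- arch$slots$role[i]
        part <- manifest[[role]][r]
        if (is.na(part)) next
        center_key <- if (arch$slots$type[i] == "center_var") {
          if (role == "proximal_op") manifest$proximal_center[r] else manifest$distal_center[r]
        } else {
          "fixed"
        }
        chars[slot_idx(role, center_key)] <- get_part(part, role)
      }
      out[r] <- paste(chars, collapse = "")
    }
  }
  out
}

#' Write a library manifest and its sequences to disk
#'
#' Writes the manifest as TSV and, when sequences are present, a FASTA file
#' whose headers are the variant ids.
#'
#' @param manifest A library manifest from [enumerate_library()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_library <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path)
  paths <- manifest_path
  if ("sequence" %in% names(manifest)) {
    fasta_path <- file.path(dir, "variants.fasta")
    writeLines(
      paste0(">", manifest$variant_id, "\n", manifest$sequence),
      fasta_path
    )
    paths <- c(paths, fasta_path)
  }
  invisible(paths)
}
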