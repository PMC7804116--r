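#' Part catalog for promoter library design
#'
#' A part catalog is a tibble with one row per (name, role) pair and columns
#' `name`, `role`, `sequence` and `source`. Roles identify the slot a part may
#' occupy: the LacI operator slots (`proximal_op`, `distal_op`,
#' `distalplus_op`, `spacer_op`, `core_op`), the sigma70 recognition elements
#' (`minus10`, `minus35`), the AT-rich `up_element`, the 3 bp extended -10
#' motif (`ext10`) and the promoter `backbone` the parts are placed onto.
#'
#' @section Shipped catalog:
#' The package ships a default catalog with the ten LacI operator variants
#' used in the two-operator combinatorial design (native O_1 and O_3, a
#' 3-mutation O_2 variant, the symmetrised O_sym, half-site palindromes and a
#' scrambled negative-control operator O_scram), four -10 and four -35
#' elements spanning weak to consensus, four synthetic UP elements, the TGG
#' extended -10, 23 bp operator sites for six transcription factors used in
#' the operator-spacing design, and a lacUV5-like backbone. Sequences marked
#' "synthetic" in the `source` column are stand-ins; every enumeration count
#' and placement rule is independent of the actual sequences.
#'
#' @param path Path to a tab-separated catalog file with columns
#'   `name`, `role`, `sequence`, `source`.
#' @return A tibble of validated parts.
#' @examples
#' catalog <- default_catalog()
#' dplyr::count(catalog, role)
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) abort(sprintf("catalog file '%s' does not exist", path))
  parts <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("name", "role", "sequence", "source")
  missing_cols <- setdiff(required, names(parts))
  if (length(missing_cols) > 0L) {
    abort(paste0("catalog is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  validate_catalog(parts[required])
}

#' @rdname load_catalog
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "parts_catalog.tsv", package = "promotherm"))
}

part_roles <- c(
  "proximal_op", "distal_op", "distalplus_op", "spacer_op", "core_op",
  "minus10", "minus35", "up_element", "ext10", "backbone"
)

validate_catalog <- function(parts) {
  bad_role <- setdiff(unique(parts$role), part_roles)
  if (length(bad_role) > 0L) {
    abort(paste0("unknown part role(s): ", paste(bad_role, collapse = ", ")))
  }
  dup <- parts[duplicated(parts[c("name", "role")]), , drop = FALSE]
  if (nrow(dup) > 0L) {
    abort(paste0(
      "duplicate part name(s) within a role: ",
      paste(unique(paste0(dup$name, " (", dup$role, ")")), collapse = ", ")
    ))
  }
  purrr::walk2(parts$sequence, parts$name, check_dna)
  tibble::as_tibble(parts)
}

catalog_part <- function(catalog, name, role) {
  hit <- catalog[catalog$name == name & catalog$role == role, , drop = FALSE]
  if (nrow(hit) == 0L) {
    abort(sprintf("catalog has no part named '%s' with role '%s'", name, role))
  }
  hit$sequence[[1]]
}

#' Scramble an operator while preserving its base composition
#'
#' Produces a seeded random permutation of an operator sequence, the
#' construction used for scrambled-operator negative controls: the scrambled
#' site keeps the length and GC content of the native site but loses its
#' recognition sequence.
#'
#' @param part A one-row catalog tibble, or a plain DNA string.
#' @param seed Integer seed; the same part and seed always give the same
#'   scramble.
#' @return Same type as `part`, with the scrambled sequence (and, for catalog
#'   rows, `_scram` appended to the name).
#' @examples
#' scramble_operator("AATTGTGAGCGGATAACAATT", seed = 1)
#' @export
scramble_operator <- function(part, seed) {
  seq <- if (is.character(part)) part else part$sequence[[1]]
  check_dna(seq, if (is.character(part)) "operator" else part$name[[1]])
  scrambled <- withr_seed(seed, {
    paste(sample(strsplit(seq, "")[[1]]), collapse = "")
  })
  if (is.character(part)) {
    scrambled
  } else {
    out <- part
    out$sequence <- scrambled
    out$name <- paste0(out$name, "_scram")
    out$source <- paste0("scramble of ", part$name[[1]])
    out
  }
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
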