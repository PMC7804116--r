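# Promoter architectures: which slots exist, where they sit on the promoter
# axis, and how variable placements are specified. Coordinates are relative to
# the TSS (+1), there is no position 0, and operator intervals are inclusive
# 1-based genomic-style spans on the sense strand.

BACKBONE_WINDOW <- c(-130L, 50L)

#' Architecture specifications
#'
#' Returns the slot layout of one of the five promoter architectures:
#'
#' * `spacing`: a 23 bp proximal TF site centred at +12 (spanning +1 to +23)
#'   and a 23 bp distal site whose centre varies from -83 to -116.
#' * `pcombo`: 21 bp proximal operator centred at +11, -10 element at
#'   -12..-7, -35 element at -35..-30, 21 bp distal operator centred at -90.
#' * `pmultiple`: `pcombo` plus a 21 bp "distal+" operator immediately
#'   upstream of the distal operator (centred at -111).
#' * `pspacer`: a 17 bp operator filling the 17 bp spacer between the -35 and
#'   -10 hexamers (-29..-13) and a 21 bp distal operator placed at an
#'   interoperator distance of 46-56 bp.
#' * `psteric`: 21 bp core operator centred at -26 replacing the -35 element,
#'   optional TGG extended -10 at -15..-13, UP element at -52..-37, and a
#'   21 bp proximal operator centred at +11 or +30.
#'
#' @param name One of `"spacing"`, `"pcombo"`, `"pmultiple"`, `"pspacer"`,
#'   `"psteric"`.
#' @return A list with the architecture `name`, the assembled sequence
#'   `window` (positions on the TSS axis) and a tibble of `slots`.
#' @export
architecture_spec <- function(name) {
  name <- match.arg(name, c("spacing", "pcombo", "pmultiple", "pspacer", "psteric"))
  slot <- function(role, len, type, at = NA_integer_, optional = FALSE) {
    tibble::tibble(role = role, len = len, type = type, at = at, optional = optional)
  }
  spec <- switch(name,
    spacing = list(
      window = c(-127L, 23L),
      slots = dplyr::bind_rows(
        slot("proximal_op", 23L, "center", 12L),
        slot("distal_op", 23L, "center_var", optional = TRUE)
      )
    ),
    pcombo = list(
      window = c(-100L, 21L),
      slots = dplyr::bind_rows(
        slot("distal_op", 21L, "center", -90L),
        slot("minus35", 6L, "span_start", -35L),
        slot("minus10", 6L, "span_start", -12L),
        slot("proximal_op", 21L, "center", 11L)
      )
    ),
    pmultiple = list(
      window = c(-121L, 21L),
      slots = dplyr::bind_rows(
        slot("distalplus_op", 21L, "center", -111L),
        slot("distal_op", 21L, "center", -90L),
        slot("minus35", 6L, "span_start", -35L),
        slot("minus10", 6L, "span_start", -12L),
        slot("proximal_op", 21L, "center", 11L)
      )
    ),
    pspacer = list(
      window = c(-90L, 21L),
      slots = dplyr::bind_rows(
        slot("distal_op", 21L, "center_var"),
        slot("minus35", 6L, "span_start", -35L),
        slot("spacer_op", 17L, "span_start", -29L),
        slot("minus10", 6L, "span_start", -12L)
      )
    ),
    psteric = list(
      window = c(-56L, 40L),
      slots = dplyr::bind_rows(
        slot("up_element", 16L, "span_start", -52L),
        slot("core_op", 21L, "center", -26L),
        slot("ext10", 3L, "span_start", -15L, optional = TRUE),
        slot("minus10", 6L, "span_start", -12L),
        slot("proximal_op", 21L, "center_var")
      )
    )
  )
  c(list(name = name), spec)
}

# resolve the axis positions a slot occupies
slot_positions <- function(slot_row, placement) {
  if (slot_row$type == "center") {
    span_from_center(slot_row$at, slot_row$len)
  } else if (slot_row$type == "span_start") {
    axis_positions(slot_row$at, slot_row$at + slot_row$len)[seq_len(slot_row$len)]
  } else {
    center <- placement[[slot_row$role]]
    if (is.null(center)) {
      abort(sprintf("architecture requires a placement for slot '%s'", slot_row$role))
    }
    span_from_center(as.integer(center), slot_row$len)
  }
}

#' Assemble a promoter variant sequence
#'
#' Places each part onto the lacUV5-like backbone at the position its
#' architecture slot dictates and returns the assembled variant sequence.
#' Assembly is a pure function of its inputs; parts may never overlap (the
#' `psteric` core operator does not overlap the -35 element, it replaces it:
#' that architecture has no -35 slot).
#'
#' @param architecture An architecture name or the result of
#'   [architecture_spec()].
#' @param parts Named list/character vector mapping slot roles to catalog part
#'   names. Optional slots (the spacing-library distal cassette, the psteric
#'   extended -10) may be omitted.
#' @param placement Named list of variable placements: `distal_op` centre for
#'   `spacing`, `interoperator_distance` (46-56 bp) for `pspacer`,
#'   `proximal_op` centre (+11 or +30) for `psteric`.
#' @param catalog Part catalog tibble (defaults to the shipped catalog).
#' @return The assembled DNA string, with a `spans` attribute giving the
#'   occupied interval per slot.
#' @examples
#' seq <- assemble_sequence(
#'   "pcombo",
#'   parts = c(
#'     proximal_op = "O_1", distal_op = "O_sym",
#'     minus10 = "TATAAT", minus35 = "TTGACA"
#'   )
#' )
#' attr(seq, "spans")
#' @export
assemble_sequence <- function(architecture, parts, placement = list(),
                              catalog = default_catalog()) {
  arch <- if (is.character(architecture)) architecture_spec(architecture) else architecture
  placement <- as.list(placement)
  if (arch$name == "pspacer") {
    d <- placement$interoperator_distance
    if (is.null(d)) abort("pspacer placement needs an 'interoperator_distance' (46-56 bp)")
    d <- as.integer(d)
    if (d < 46L || d > 56L) abort("pspacer interoperator distance must be between 46 and 56 bp")
    # distal centre chosen so the gap to the 5' end of the -35 is d - 26 bp
    placement$distal_op <- -(20L + d)
  }
  window <- axis_positions(arch$window[1], arch$window[2])
  backbone <- strsplit(catalog_part(catalog, "lacUV5_backbone", "backbone"), "")[[1]]
  backbone_axis <- axis_positions(BACKBONE_WINDOW[1], BACKBONE_WINDOW[2])
  chars <- backbone[match(window, backbone_axis)]

  occupied <- rep(NA_character_, length(window))
  spans <- list()
  for (i in seq_len(nrow(arch$slots))) {
    row <- arch$slots[i, ]
    part_name <- parts[[row$role]]
    if (is.null(part_name) || is.na(part_name)) {
      if (row$optional) next
      abort(sprintf("architecture '%s' requires a part for slot '%s'", arch$name, row$role))
    }
    seq <- catalog_part(catalog, part_name, row$role)
    if (nchar(seq) != row$len) {
      abort(sprintf(
        "part '%s' is %d bp but slot '%s' of '%s' requires %d bp",
        part_name, nchar(seq), row$role, arch$name, row$len
      ))
    }
    pos <- slot_positions(row, placement)
    idx <- match(pos, window)
    if (anyNA(idx)) {
      abort(sprintf("slot '%s' falls outside the %s assembly window", row$role, arch$name))
    }
    clash <- occupied[idx]
    if (any(!is.na(clash))) {
      abort(sprintf(
        "slots '%s' and '%s' overlap in architecture '%s'",
        stats::na.omit(clash)[1], row$role, arch$name
      ))
    }
    occupied[idx] <- row$role
    chars[idx] <- strsplit(seq, "")[[1]]
    spans[[row$role]] <- tibble::tibble(
      role = row$role, part = part_name,
      start = pos[1], end = pos[length(pos)]
    )
  }
  out <- paste(chars, collapse = "")
  attr(out, "spans") <- dplyr::bind_rows(spans)
  out
}
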