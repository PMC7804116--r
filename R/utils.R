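# shared helpers: DNA string utilities and the gapped promoter coordinate axis

DNA_ALPHABET <- c("A", "C", "G", "T")

check_dna <- function(sequence, name = "sequence") {
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), DNA_ALPHABET)
  if (nchar(sequence) == 0L) {
    abort(sprintf("part '%s' has an empty sequence", name))
  }
  if (length(bad) > 0L) {
    abort(sprintf(
      "part '%s' contains characters outside A/C/G/T: %s",
      name, paste(bad, collapse = ", ")
    ))
  }
  invisible(sequence)
}

reverse_complement <- function(sequence) {
  chartr(
    "ACGT", "TGCA",
    vapply(
      strsplit(sequence, ""),
      function(x) paste(rev(x), collapse = ""), character(1)
    )
  )
}

gc_fraction <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  mean(chars %in% c("G", "C"))
}

# Promoter coordinates are genomic-style relative to the transcription start
# site: the TSS is +1 and there is no position 0. All placement arithmetic
# runs on this gapped axis.

#' @noRd
axis_positions <- function(from, to) {
  stopifnot(from <= to)
  p <- seq.int(from, to)
  p[p != 0L]
}

# interval of length `len` whose midpoint is `center` on the gapped axis;
# for even lengths the declared centre is the middle position nearer the TSS
span_from_center <- function(center, len) {
  if (center == 0L) abort("there is no position 0 on the promoter axis")
  positions <- axis_positions(center - len - 1L, center + len + 1L)
  i <- match(center, positions)
  left_offset <- if (len %% 2L == 1L) {
    (len - 1L) %/% 2L
  } else if (center > 0L) {
    len %/% 2L - 1L
  } else {
    len %/% 2L
  }
  positions[seq.int(i - left_offset, length.out = len)]
}

# distance between two positions on the gapped axis (number of steps,
# skipping the absent position 0)
axis_distance <- function(a, b) {
  abs(a - b) - as.integer(sign(a) != sign(b))
}
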