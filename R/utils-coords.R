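#' Convert 1-based closed coordinates to 0-based half-open
#'
#' GFF3 and most biological flat files use 1-based closed intervals; all
#' internal interval arithmetic in this package is 0-based half-open, which
#' makes region slicing and length computation (`end - start`) gap-free.
#'
#' @param start,end integer vectors, 1-based closed.
#' @return data.frame with columns `start`, `end` (0-based half-open).
#' @export
coords_to_internal <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  data.frame(start = start - 1L, end = as.integer(end))
}

#' Convert 0-based half-open coordinates back to 1-based closed
#'
#' Inverse of [coords_to_internal()]; the two form an involution.
#'
#' @param start,end integer vectors, 0-based half-open.
#' @return data.frame with columns `start`, `end` (1-based closed).
#' @export
coords_to_gff <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  data.frame(start = as.integer(start + 1L), end = as.integer(end))
}

#' Infer the subgenome from a chromosome name
#'
#' Hexaploid wheat chromosomes are conventionally named `<number><subgenome>`
#' ("1A", "chr3D", ...). The default pattern captures a trailing A/B/D that
#' follows a digit; anything that does not match (scaffolds, "Un", organelles)
#' maps to `"unknown"` and is excluded from subgenome-dependent classification.
#'
#' @param chromosome character vector of chromosome names.
#' @param pattern regular expression with one capture group yielding the
#'   subgenome letter.
#' @return character vector of subgenome labels (`"A"`, `"B"`, `"D"` or
#'   `"unknown"`).
#' @export
subgenome_from_chromosome <- function(chromosome, pattern = "[0-9]([ABD])$") {
  m <- regmatches(chromosome, regexec(pattern, chromosome))
  vapply(m, function(x) if (length(x) >= 2) x[2] else "unknown", character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

round_half_even <- function(x, digits) round(x, digits)
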