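#' The amyloid-beta 1-42 sequence
#'
#' Single-letter sequence of human A\eqn{\beta_{1-42}}, the 42-residue
#' amyloid-\eqn{\beta} peptide.
#'
#' @return A length-one character string (42 residues).
#' @export
#' @examples
#' nchar(abeta42_sequence())
abeta42_sequence <- function() {
  "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
}

#' Standard fragment windows P1-P7
#'
#' The seven overlapping 10-12 residue windows along A\eqn{\beta_{1-42}}
#' screened by the pipeline: 1-10 (P1), 6-15 (P2), 11-20 (P3), 16-25 (P4),
#' 21-30 (P5), 26-36 (P6) and 31-42 (P7); 1-based inclusive coordinates.
#'
#' @return A tibble with columns `name`, `start`, `end`.
#' @export
#' @examples
#' abeta_fragment_ranges()
abeta_fragment_ranges <- function() {
  tibble::tibble(
    name  = paste0("P", 1:7),
    start = c(1L, 6L, 11L, 16L, 21L, 26L, 31L),
    end   = c(10L, 15L, 20L, 25L, 30L, 36L, 42L)
  )
}

AA_CODES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

validate_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || anyNA(sequence) || any(!nzchar(sequence))) {
    abort(sprintf("`%s` must be a non-empty character vector of residue strings.", arg))
  }
  bad <- purrr::map_lgl(strsplit(toupper(sequence), ""), function(x) {
    any(!x %in% AA_CODES)
  })
  if (any(bad)) {
    offenders <- unique(unlist(lapply(
      strsplit(toupper(sequence[bad]), ""),
      function(x) setdiff(x, AA_CODES)
    )))
    abort(sprintf(
      "Non-standard residue code(s) %s; only the 20 standard one-letter codes are accepted.",
      paste(sQuote(offenders), collapse = ", ")
    ))
  }
  toupper(sequence)
}

#' Construct a peptide table
#'
#' Builds a validated one-row-per-peptide tibble. Sequences must use the 20
#' standard one-letter residue codes; anything else is rejected (silently
#' skipping unknown codes would corrupt downstream charge sums).
#'
#' @param name Character vector of peptide labels.
#' @param sequence Character vector of residue strings (same length).
#' @param n_acetylated,c_amidated Logical; terminal modification flags.
#' @param start,end Optional 1-based inclusive position of the peptide in a
#'   parent sequence; when given, `end - start + 1` must equal the sequence
#'   length.
#'
#' @return A tibble with columns `name`, `sequence`, `length`,
#'   `n_acetylated`, `c_amidated`, `start`, `end`.
#' @export
#' @examples
#' peptide("KLVFFAE-frag", "KLVFFAE")
peptide <- function(name, sequence, n_acetylated = FALSE, c_amidated = FALSE,
                    start = NA_integer_, end = NA_integer_) {
  sequence <- validate_sequence(sequence)
  out <- tibble::tibble(
    name = as.character(name),
    sequence = sequence,
    length = nchar(sequence),
    n_acetylated = n_acetylated,
    c_amidated = c_amidated,
    start = as.integer(start),
    end = as.integer(end)
  )
  bad <- !is.na(out$start) & !is.na(out$end) &
    (out$end - out$start + 1L) != out$length
  if (any(bad)) {
    abort(sprintf(
      "Parent range does not match sequence length for: %s.",
      paste(out$name[bad], collapse = ", ")
    ))
  }
  out
}

#' Extract fragment windows from a parent peptide
#'
#' Cuts subsequences out of a parent sequence at the given 1-based inclusive
#' intervals. Intervals may overlap. The resulting fragments are flagged as
#' N-terminally acetylated and C-terminally amidated by default, matching
#' how screening fragments are synthesised (capped termini remove the charges
#' of the free terminal amine and carboxyl groups).
#'
#' @param parent A single-row peptide tibble (see [peptide()]) or a character
#'   string holding the parent sequence.
#' @param ranges A data frame with columns `start` and `end` (1-based,
#'   inclusive) and optionally `name`; defaults to [abeta_fragment_ranges()].
#' @param n_acetylated,c_amidated Terminal modification flags applied to every
#'   fragment.
#'
#' @return A peptide tibble with one row per interval, in input order.
#' @export
#' @examples
#' frags <- fragment_windows(abeta42_sequence())
#' frags[, c("name", "sequence", "length")]
fragment_windows <- function(parent, ranges = abeta_fragment_ranges(),
                             n_acetylated = TRUE, c_amidated = TRUE) {
  if (is.character(parent)) parent <- peptide("parent", parent)
  stopifnot(is.data.frame(parent), nrow(parent) == 1L)
  stopifnot(is.data.frame(ranges), all(c("start", "end") %in% names(ranges)))
  seq_parent <- parent$sequence[[1]]
  n <- nchar(seq_parent)
  start <- as.integer(ranges$start)
  end <- as.integer(ranges$end)
  bad <- which(is.na(start) | is.na(end) | start < 1L | end > n | start > end)
  if (length(bad)) {
    abort(sprintf(
      "Interval (%d, %d) is outside the parent sequence (length %d).",
      start[bad[1]], end[bad[1]], n
    ))
  }
  nm <- if ("name" %in% names(ranges)) as.character(ranges$name) else
    sprintf("%s_%d_%d", parent$name[[1]], start, end)
  peptide(
    name = nm,
    sequence = substring(seq_parent, start, end),
    n_acetylated = n_acetylated,
    c_amidated = c_amidated,
    start = start,
    end = end
  )
}
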