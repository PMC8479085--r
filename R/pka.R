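#' Side-chain and terminal pKa table (Bjellqvist/ProtParam convention)
#'
#' The pKa set used by the ExPASy ProtParam pI calculation, after Bjellqvist
#' and co-workers: side-chain values for the seven ionizable residues plus
#' terminal pKas, with residue-specific variants for the N-terminal amine
#' (depends on the first residue) and for the C-terminal carboxyl when the
#' last residue is Asp or Glu.
#'
#' @return A list with elements
#'   `side` (named numeric pKas for D, E, C, Y, H, K, R),
#'   `sign` (named, `"acidic"` or `"basic"` per side chain),
#'   `nterm_default`, `nterm_by_residue`, `cterm_default`, `cterm_by_residue`.
#' @export
#' @examples
#' pka_bjellqvist()$side[["H"]]
pka_bjellqvist <- function() {
  list(
    side = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0, H = 5.98, K = 10.0, R = 12.0),
    sign = c(D = "acidic", E = "acidic", C = "acidic", Y = "acidic",
             H = "basic", K = "basic", R = "basic"),
    nterm_default = 7.50,
    nterm_by_residue = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36,
                         T = 6.82, V = 7.44, E = 7.70),
    cterm_default = 3.55,
    cterm_by_residue = c(D = 4.55, E = 4.75)
  )
}

validate_pka_table <- function(table) {
  needed <- c("side", "sign", "nterm_default", "nterm_by_residue",
              "cterm_default", "cterm_by_residue")
  if (!is.list(table) || !all(needed %in% names(table))) {
    abort("`table` must be a pKa table as returned by `pka_bjellqvist()`.")
  }
  vals <- c(table$side, table$nterm_default, table$nterm_by_residue,
            table$cterm_default, table$cterm_by_residue)
  if (any(vals <= 0 | vals >= 14)) abort("All pKa values must lie in (0, 14).")
  table
}

# Ionizable sites of one sequence under a pKa table: tibble(pka, sign).
# Terminal sites included only when the termini carry free amine/carboxyl.
ionizable_sites <- function(sequence, table, free_termini) {
  res <- strsplit(sequence, "")[[1]]
  side_idx <- res[res %in% names(table$side)]
  sites <- tibble::tibble(
    pka = unname(table$side[side_idx]),
    sign = unname(table$sign[side_idx])
  )
  if (free_termini) {
    first <- res[1]
    last <- res[length(res)]
    nt <- table$nterm_by_residue[first]
    if (is.na(nt)) nt <- table$nterm_default
    ct <- table$cterm_by_residue[last]
    if (is.na(ct)) ct <- table$cterm_default
    sites <- dplyr::bind_rows(
      sites,
      tibble::tibble(pka = c(unname(nt), unname(ct)),
                     sign = c("basic", "acidic"))
    )
  }
  sites
}

#' Henderson-Hasselbalch net charge of a peptide
#'
#' Net charge in elementary-charge units at a given pH: each basic site
#' contributes \eqn{1/(1+10^{pH-pK_a})}, each acidic site
#' \eqn{-1/(1+10^{pK_a-pH})}. Terminal amine/carboxyl sites are counted only
#' with `free_termini = TRUE`; capped (acetylated/amidated) peptides should
#' use `free_termini = FALSE`.
#'
#' @param peptides A peptide tibble (see [peptide()]) or character vector of
#'   sequences.
#' @param pH Numeric scalar in \[0, 14\].
#' @param table A pKa table; default [pka_bjellqvist()].
#' @param free_termini Include the terminal charge sites? Default `TRUE`, the
#'   convention under which ProtParam-style pIs are reported.
#'
#' @return Numeric vector of net charges, one per peptide.
#' @export
#' @examples
#' net_charge("KLVFFAE", pH = 7)
net_charge <- function(peptides, pH, table = pka_bjellqvist(),
                       free_termini = TRUE) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- validate_sequence(peptides, "peptides")
  stopifnot(is.numeric(pH), length(pH) == 1L)
  if (pH < 0 || pH > 14) abort("`pH` must lie in [0, 14].")
  table <- validate_pka_table(table)
  purrr::map_dbl(peptides, function(s) {
    sites <- ionizable_sites(s, table, free_termini)
    basic <- sites$sign == "basic"
    sum(1 / (1 + 10^(pH - sites$pka[basic]))) -
      sum(1 / (1 + 10^(sites$pka[!basic] - pH)))
  })
}

#' Theoretical isoelectric point
#'
#' pH of zero Henderson-Hasselbalch net charge, found by bisection on
#' \[0, 14\]. With the default Bjellqvist table and free termini this matches
#' the ExPASy ProtParam "theoretical pI". Values are reported rounded to two
#' decimals (set `digits = NULL` to disable rounding).
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units before rounding.
#' @param digits Decimals for the reported pI; `NULL` for the raw root.
#'
#' @return Numeric vector of pI values, one per peptide.
#' @export
#' @examples
#' isoelectric_point("DAEFRHDSGY") # N-terminal decapeptide of Abeta 1-42
isoelectric_point <- function(peptides, table = pka_bjellqvist(),
                              free_termini = TRUE, tol = 1e-3, digits = 2) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- validate_sequence(peptides, "peptides")
  table <- validate_pka_table(table)
  out <- purrr::map_dbl(peptides, function(s) {
    f <- function(pH) {
      sites <- ionizable_sites(s, table, free_termini)
      basic <- sites$sign == "basic"
      sum(1 / (1 + 10^(pH - sites$pka[basic]))) -
        sum(1 / (1 + 10^(sites$pka[!basic] - pH)))
    }
    lo <- 0; hi <- 14
    flo <- f(lo); fhi <- f(hi)
    if (flo <= 0 || fhi >= 0) {
      abort(sprintf(
        "No isoelectric point: net charge of '%s' does not cross zero on [0, 14].", s
      ))
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Tabulate sequence properties for a set of peptides
#'
#' Convenience wrapper producing the screening table: name, sequence, length,
#' net charge at a reference pH and theoretical pI.
#'
#' @param peptides A peptide tibble.
#' @param pH Reference pH for the net-charge column (default 7.2, the assay
#'   buffer).
#' @inheritParams net_charge
#' @return The input tibble with `charge` and `pI` columns appended.
#' @export
#' @examples
#' peptide_properties(fragment_windows(abeta42_sequence()))
peptide_properties <- function(peptides, pH = 7.2, table = pka_bjellqvist(),
                               free_termini = TRUE) {
  stopifnot(is.data.frame(peptides))
  dplyr::mutate(
    peptides,
    charge = net_charge(.data$sequence, pH = pH, table = table,
                        free_termini = free_termini),
    pI = isoelectric_point(.data$sequence, table = table,
                           free_termini = free_termini)
  )
}

#' Read peptides from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @inheritParams peptide
#' @return A peptide tibble.
#' @export
read_peptides_fasta <- function(path, n_acetylated = FALSE, c_amidated = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Package 'Biostrings' is required to read FASTA files.")
  }
  ss <- Biostrings::readAAStringSet(path)
  peptide(names(ss), unname(as.character(ss)),
          n_acetylated = n_acetylated, c_amidated = c_amidated)
}

#' Write peptides to a FASTA file
#'
#' @param peptides A peptide tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptides_fasta <- function(peptides, path) {
  stopifnot(is.data.frame(peptides))
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Package 'Biostrings' is required to write FASTA files.")
  }
  ss <- Biostrings::AAStringSet(setNames(peptides$sequence, peptides$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
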