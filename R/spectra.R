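#' @keywords internal
SPECTRUM_KEYS <- c("sample_id", "modality", "axis_kind", "replicate", "time_h")

AXIS_KINDS <- c("wavelength_nm", "wavenumber_cm1")

#' Construct a single-spectrum tibble
#'
#' One acquisition: an ordered axis (nm or cm\eqn{^{-1}}) with one intensity
#' per point, tagged with sample, modality, incubation time and replicate.
#' Collections of spectra (a spectral series) are simply row-bound spectrum
#' tibbles; every operation in the package works on the long format.
#'
#' @param axis Strictly monotone numeric axis (length \eqn{\ge} 2).
#' @param intensity Numeric intensities, one per axis point.
#' @param axis_kind `"wavelength_nm"` or `"wavenumber_cm1"`.
#' @param sample_id Sample label.
#' @param modality Modality label, e.g. `"tht_fluorescence"`, `"emission"`,
#'   `"scattering"`, `"ftir"`, `"cd"`.
#' @param time_h Incubation time in hours (\eqn{\ge} 0).
#' @param replicate Replicate index.
#'
#' @return A validated spectra tibble with columns
#'   `sample_id`, `modality`, `axis_kind`, `replicate`, `time_h`, `axis`,
#'   `intensity`.
#' @export
#' @examples
#' spectrum(470:490, dnorm(470:490, 480, 5), sample_id = "demo")
spectrum <- function(axis, intensity, axis_kind = "wavelength_nm",
                     sample_id = "sample", modality = "emission",
                     time_h = 0, replicate = 1L) {
  n <- length(axis)
  out <- tibble::new_tibble(list(
    sample_id = rep_len(as.character(sample_id), n),
    modality = rep_len(as.character(modality), n),
    axis_kind = rep_len(as.character(axis_kind), n),
    replicate = rep_len(as.integer(replicate), n),
    time_h = rep_len(as.numeric(time_h), n),
    axis = as.numeric(axis),
    intensity = as.numeric(intensity)
  ), nrow = n)
  as_spectra(out)
}

#' Validate a spectra tibble
#'
#' Checks the long-format contract: required columns present, a known axis
#' kind, non-negative times, and within each acquisition (one
#' sample/modality/replicate/time combination) a strictly monotone axis with
#' at least two points.
#'
#' @param x A data frame in long spectra format.
#' @return `x` as a tibble, invisibly validated.
#' @export
as_spectra <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c(SPECTRUM_KEYS, "axis", "intensity")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(sprintf("Spectra table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  if (any(!x$axis_kind %in% AXIS_KINDS)) {
    abort(sprintf("`axis_kind` must be one of %s.",
                  paste(sQuote(AXIS_KINDS), collapse = ", ")))
  }
  if (any(x$time_h < 0)) abort("`time_h` must be non-negative.")
  if (anyNA(x$axis) || anyNA(x$intensity)) {
    abort("`axis` and `intensity` must not contain NA.")
  }
  key <- do.call(paste, c(unclass(x[SPECTRUM_KEYS]), sep = "\r"))
  axes <- split(x$axis, key)
  if (any(lengths(axes) < 2)) {
    abort("Each spectrum needs at least 2 axis points.")
  }
  mono <- vapply(axes, function(a) {
    d <- diff(a)
    all(d > 0) || all(d < 0)
  }, logical(1))
  if (any(!mono)) {
    bad <- x[match(names(mono)[!mono][1], key), ]
    abort(sprintf(
      "Axis is not strictly monotone for sample '%s' at t = %g h (replicate %d).",
      bad$sample_id, bad$time_h, bad$replicate
    ))
  }
  x
}

# Split a spectra tibble into a list of single spectra (keeps key order).
split_spectra <- function(x) {
  key <- interaction(x[SPECTRUM_KEYS], drop = TRUE, lex.order = TRUE)
  split(x, key)
}

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", hdr))
  kv <- kv[lengths(kv) == 3]
  setNames(vapply(kv, `[`, "", 3), vapply(kv, `[`, "", 2))
}

#' Read spectra from a delimited text file
#'
#' Reads the package's plain-text spectra formats. Files start with
#' `# key: value` metadata lines (keys `modality`, `axis_kind`, `sample_id`,
#' optionally `units` and, for wide files, `replicate`), followed by a
#' delimited table:
#' * **long** dialect: columns `axis`, `intensity`, `time_h`, `replicate`;
#' * **wide** dialect: first column `axis`, remaining columns named by their
#'   numeric incubation time in hours.
#'
#' @param path File path.
#' @param dialect `"long"` or `"wide"`.
#' @param delim Field delimiter (default `,`).
#' @return A validated spectra tibble (see [spectrum()]).
#' @export
read_spectra <- function(path, dialect = c("long", "wide"), delim = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  meta <- parse_header(lines)
  for (key in c("modality", "axis_kind", "sample_id")) {
    if (!key %in% names(meta)) {
      abort(sprintf("Header of '%s' is missing '# %s: ...'.", path, key))
    }
  }
  body <- lines[!grepl("^#", lines)]
  # base parser: strtod is correctly rounded, so written doubles round-trip
  tab <- utils::read.csv(text = paste(body, collapse = "\n"), sep = delim,
                         check.names = FALSE)
  if (dialect == "long") {
    missing <- setdiff(c("axis", "intensity", "time_h", "replicate"), names(tab))
    if (length(missing)) {
      abort(sprintf("Long-dialect file '%s' is missing column(s): %s (first data line %d).",
                    path, paste(missing, collapse = ", "),
                    which(!grepl("^#", lines))[1]))
    }
    out <- tibble::tibble(
      sample_id = meta[["sample_id"]],
      modality = meta[["modality"]],
      axis_kind = meta[["axis_kind"]],
      replicate = as.integer(tab$replicate),
      time_h = as.numeric(tab$time_h),
      axis = as.numeric(tab$axis),
      intensity = as.numeric(tab$intensity)
    )
  } else {
    if (names(tab)[1] != "axis") {
      abort(sprintf("Wide-dialect file '%s' must have 'axis' as first column.", path))
    }
    times <- suppressWarnings(as.numeric(names(tab)[-1]))
    if (anyNA(times)) {
      abort(sprintf("Wide-dialect columns of '%s' must be named by numeric times.", path))
    }
    rep_id <- as.integer(meta["replicate"] %||% "1")
    out <- tidyr::pivot_longer(tab, -"axis", names_to = "time_h",
                               values_to = "intensity") %>%
      dplyr::mutate(
        sample_id = meta[["sample_id"]],
        modality = meta[["modality"]],
        axis_kind = meta[["axis_kind"]],
        replicate = rep_id,
        time_h = as.numeric(.data$time_h)
      ) %>%
      dplyr::select(dplyr::all_of(c(SPECTRUM_KEYS, "axis", "intensity")))
  }
  out <- dplyr::arrange(out, .data$replicate, .data$time_h, .data$axis)
  as_spectra(out)
}

#' Write spectra to a delimited text file
#'
#' Inverse of [read_spectra()]; values round-trip exactly (full double
#' precision is written).
#'
#' @param spectra A spectra tibble covering a single `sample_id`.
#' @param path Output path.
#' @param dialect `"long"` or `"wide"` (wide requires a single replicate).
#' @param units Intensity unit label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, dialect = c("long", "wide"),
                          units = "a.u.") {
  dialect <- match.arg(dialect)
  spectra <- as_spectra(spectra)
  if (dplyr::n_distinct(spectra$sample_id) != 1L ||
      dplyr::n_distinct(spectra$modality) != 1L) {
    abort("`write_spectra()` writes one sample/modality per file.")
  }
  hdr <- c(
    sprintf("# modality: %s", spectra$modality[[1]]),
    sprintf("# axis_kind: %s", spectra$axis_kind[[1]]),
    sprintf("# sample_id: %s", spectra$sample_id[[1]]),
    sprintf("# units: %s", units)
  )
  if (dialect == "long") {
    body <- spectra %>%
      dplyr::select("axis", "intensity", "time_h", "replicate")
  } else {
    if (dplyr::n_distinct(spectra$replicate) != 1L) {
      abort("Wide dialect holds a single replicate per file.")
    }
    hdr <- c(hdr, sprintf("# replicate: %d", spectra$replicate[[1]]))
    body <- spectra %>%
      dplyr::select("axis", "time_h", "intensity") %>%
      tidyr::pivot_wider(names_from = "time_h", values_from = "intensity")
  }
  # %.17g keeps doubles bit-exact through the text round trip
  cells <- vapply(body, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(body)))
  cells <- matrix(cells, nrow = nrow(body))
  rows <- apply(cells, 1, paste, collapse = ",")
  writeLines(c(hdr, paste(names(body), collapse = ","), rows), path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x) || is.na(x)) y else x
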