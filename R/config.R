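#' Default run configuration
#'
#' All assay defaults in one record: averaging windows (ThT 475–485 nm,
#' scattering 550–555 nm, plateau 32–48 h, RET Phe 270–290 / Tyr 300–320
#' nm), the 13-point order-2 Savitzky–Golay settings, the concentration
#' correction 0.7, the mixture scale 2, the Förster distance 13.5 Å, the
#' Bjellqvist pKa table id and a master seed. Every value can be overridden
#' in a YAML run config.
#'
#' @return A named list.
#' @export
default_run_config <- function() {
  list(
    windows = list(
      tht = c(475, 485),
      scattering = c(550, 555),
      plateau_h = c(32, 48),
      ret_phe = c(270, 290),
      ret_tyr = c(300, 320)
    ),
    savitzky_golay = list(points = 13L, order = 2L, edge = "reflect"),
    correction = 0.7,
    ret_scale = 2,
    forster_r0 = 13.5,
    pka_table = "bjellqvist",
    seed = 1L,
    fragments = as.list(
      purrr::pmap(abeta_fragment_ranges(),
                  function(name, start, end) {
                    list(name = name, start = start, end = end)
                  })
    )
  )
}

config_schema <- function() {
  list(
    windows = function(x) {
      is.list(x) &&
        all(vapply(x, function(w) is.numeric(w) && length(w) == 2 &&
                     w[1] < w[2], TRUE))
    },
    savitzky_golay = function(x) {
      is.list(x) && x$points %% 2 == 1 && x$order < x$points &&
        x$edge %in% c("reflect", "fit")
    },
    correction = function(x) is.numeric(x) && x > 0 && x <= 1,
    ret_scale = function(x) is.numeric(x) && x > 0,
    forster_r0 = function(x) is.numeric(x) && x > 0,
    pka_table = function(x) identical(x, "bjellqvist"),
    seed = function(x) is.numeric(x) && x == as.integer(x),
    fragments = function(x) {
      is.list(x) && all(vapply(x, function(f) {
        all(c("name", "start", "end") %in% names(f)) && f$start <= f$end
      }, TRUE))
    }
  )
}

#' Validate a run configuration
#'
#' Checks every key against the configuration schema and reports all
#' offending keys at once.
#'
#' @param config A configuration list (e.g. from [read_run_config()]).
#' @return The validated config, invisibly usable downstream.
#' @export
validate_run_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  bad <- names(schema)[vapply(names(schema), function(key) {
    !key %in% names(config) || !isTRUE(schema[[key]](config[[key]]))
  }, TRUE)]
  if (length(bad)) {
    abort(sprintf("Invalid or missing config key(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  config
}

#' Read a YAML run configuration
#'
#' Reads a YAML file, fills unspecified keys from [default_run_config()] and
#' validates the result. Windows given in YAML as two-element sequences.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
    user <- yaml::read_yaml(path)
    for (key in names(user)) {
      if (is.list(config[[key]]) && is.list(user[[key]]) &&
          !is.null(names(config[[key]])) && key != "fragments") {
        config[[key]] <- modifyList(config[[key]], user[[key]])
      } else {
        config[[key]] <- user[[key]]
      }
    }
    # YAML reads numeric pairs as lists of length 2 sometimes; normalise
    config$windows <- lapply(config$windows, function(w) as.numeric(unlist(w)))
  }
  validate_run_config(config)
}

#' Write a machine-readable run manifest
#'
#' Records inputs, parameters, package version and seeds of a run alongside
#' its outputs for reproducibility.
#'
#' @param path Output JSON path.
#' @param config The run configuration used.
#' @param inputs Character vector of input file paths (hashed if present).
#' @param extra Optional named list of extra fields.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character(), extra = list()) {
  hashes <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- c(
    list(
      package = "fragscreen",
      version = as.character(utils::packageVersion("fragscreen")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      config = config,
      inputs = as.list(setNames(hashes, inputs))
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
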