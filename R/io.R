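# File formats: one shared CSV dialect (comma-separated, period decimal,
# UTF-8, header required, columns X_uM, Y_uM, replicate, output), JSON for
# reports/manifests, and flat key=value files for parameter sets.

.num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

parse_strict_numeric <- function(x, column, allow_na = FALSE) {
  x <- trimws(x)
  bad <- !grepl(.num_re, x)
  if (allow_na) bad <- bad & !(x %in% c("NA", ""))
  abort_if(any(bad),
           sprintf("column '%s': unparseable numeric value(s) in row(s) %s (decimal commas and locale formats are rejected)",
                   column, paste(which(bad), collapse = ", ")))
  suppressWarnings(as.numeric(ifelse(x %in% c("NA", ""), NA, x)))
}

#' Write / read a dose-response table as CSV
#'
#' The dialect is strict: comma separator, period decimal, UTF-8, header
#' `X_uM,Y_uM,replicate,output`.  Numeric fields are written with 17
#' significant digits so a write/read round trip reproduces the table
#' exactly.  Table metadata, when present, goes to a JSON sidecar
#' `<path>.json`.
#'
#' @param t a [dose_response_table()].
#' @param path output CSV path.
#' @return `write_dose_response_csv` returns `path` invisibly;
#'   `read_dose_response_csv` returns a validated [dose_response_table()].
#' @export
write_dose_response_csv <- function(t, path) {
  stopifnot(inherits(t, "dose_response_table"))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c("X_uM,Y_uM,replicate,output",
             paste(fmt(t$X_uM), fmt(t$Y_uM), t$replicate, fmt(t$output),
                   sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  md <- attr(t, "metadata")
  if (length(md))
    jsonlite::write_json(md, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  abort_if(!file.exists(path), sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("X_uM", "Y_uM", "replicate", "output")
  abort_if(anyDuplicated(names(raw)) > 0, "duplicate column names")
  missing_cols <- setdiff(need, names(raw))
  abort_if(length(missing_cols) > 0,
           sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  X <- parse_strict_numeric(raw$X_uM, "X_uM")
  Y <- parse_strict_numeric(raw$Y_uM, "Y_uM")
  rep_idx <- parse_strict_numeric(raw$replicate, "replicate")
  out <- parse_strict_numeric(raw$output, "output", allow_na = TRUE)
  md <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) md <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dose_response_table(X, Y, as.integer(rep_idx), out, metadata = md)
}

#' Write / read a flat key-value parameter configuration
#'
#' One `key = value` pair per line; `#` starts a comment; values that look
#' numeric are converted, `TRUE`/`FALSE` become logicals, everything else
#' stays character.
#'
#' @param config named list of scalar values.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   named list.
#' @export
write_config <- function(config, path) {
  abort_if(is.null(names(config)) || any(names(config) == ""),
           "all config entries must be named")
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, character(1))
  writeLines(paste(names(config), vals, sep = " = "), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  abort_if(!file.exists(path), sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  abort_if(any(bad), sprintf("malformed config line(s): %s",
                             paste(lines[bad], collapse = "; ")))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  abort_if(anyDuplicated(keys) > 0,
           sprintf("duplicate config key(s): %s",
                   paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  parsed <- lapply(vals, function(v) {
    if (grepl(.num_re, v)) as.numeric(v)
    else if (v %in% c("TRUE", "FALSE")) as.logical(v)
    else v
  })
  stats::setNames(parsed, keys)
}

#' Flatten circuit parameters to a config list (and back)
#'
#' The flat key-value serialization of a [full_circuit_params()] object:
#' sensor fields are prefixed `sX_` / `sY_`, everything else keeps its
#' field name.  `params_from_config` reconstructs the object, filling
#' unspecified keys from [default_full_params()].
#'
#' @param p a [full_circuit_params()].
#' @return `params_to_config`: a named list; `params_from_config`: a
#'   [full_circuit_params()].
#' @export
params_to_config <- function(p) {
  stopifnot(inherits(p, "full_circuit_params"))
  sx <- p$sensor_X; sy <- p$sensor_Y
  c(stats::setNames(lapply(c("regulator_total", "inducer_Kd", "dna_Kd",
                             "dna_copies", "max_rate", "hill"),
                           function(f) sx[[f]]),
                    paste0("sX_", c("regulator_total", "inducer_Kd", "dna_Kd",
                                    "dna_copies", "max_rate", "hill"))),
    stats::setNames(lapply(c("regulator_total", "inducer_Kd", "dna_Kd",
                             "dna_copies", "max_rate", "hill"),
                           function(f) sy[[f]]),
                    paste0("sY_", c("regulator_total", "inducer_Kd", "dna_Kd",
                                    "dna_copies", "max_rate", "hill"))),
    list(delta_X = p$delta_X, delta_Y = p$delta_Y,
         a5 = p$a5, b5 = p$b5, k5 = p$k5,
         a6 = p$a6, b6 = p$b6, k6 = p$k6,
         R_tot = p$R_tot, d0 = p$d0,
         a = p$a, b = p$b, k = p$k, gamma = p$gamma,
         protease_tag = p$protease_tag, gfp_per_uM = p$gfp_per_uM))
}

#' @rdname params_to_config
#' @param config named list, e.g. from [read_config()]; keys as produced by
#'   [params_to_config()].
#' @export
params_from_config <- function(config) {
  base <- params_to_config(default_full_params())
  unknown <- setdiff(names(config), names(base))
  abort_if(length(unknown) > 0,
           sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  base[names(config)] <- config
  sens <- function(prefix, mode) {
    g <- function(f) base[[paste0(prefix, f)]]
    sensor_params(g("regulator_total"), g("inducer_Kd"), g("dna_Kd"),
                  g("dna_copies"), g("max_rate"), mode = mode,
                  hill = g("hill"))
  }
  full_circuit_params(
    sensor_X = sens("sX_", "repressor"), sensor_Y = sens("sY_", "activator"),
    delta_X = base$delta_X, delta_Y = base$delta_Y,
    a5 = base$a5, b5 = base$b5, k5 = base$k5,
    a6 = base$a6, b6 = base$b6, k6 = base$k6,
    R_tot = base$R_tot, d0 = base$d0,
    a = base$a, b = base$b, k = base$k, gamma = base$gamma,
    protease_tag = base$protease_tag, gfp_per_uM = base$gfp_per_uM)
}
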