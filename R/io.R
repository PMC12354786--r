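# Curve CSV dialect: header
#   time_s,lambda_ax,lambda_tr,force_per_width_N_per_m[,segment]
# comma-separated, UTF-8, '.' decimal; segment entries "<cycle>:loading"
# or "<cycle>:unloading".

curve_csv_header <- c("time_s", "lambda_ax", "lambda_tr",
                      "force_per_width_N_per_m")

#' Read a tensile curve from CSV
#'
#' Reads the standard curve dialect. A `segment` column, when present,
#' yields a `cyclic_curve` with cycle indices and loading/unloading
#' phases; otherwise a plain `tensile_curve` is returned.
#'
#' @param path CSV file path.
#' @return A `tensile_curve` or `cyclic_curve`.
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) {
    stop_wallmech("wallmech_io", paste0("file not found: ", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  need <- curve_csv_header
  if (!all(need %in% names(df))) {
    stop_wallmech(
      "wallmech_schema",
      paste0("missing column(s): ",
             paste(setdiff(need, names(df)), collapse = ", "),
             "; expected header: ",
             paste(c(need, "[segment]"), collapse = ","))
    )
  }
  extra <- setdiff(names(df), c(need, "segment"))
  if (length(extra)) {
    stop_wallmech("wallmech_schema",
                  paste0("unknown column(s): ", paste(extra, collapse = ", ")))
  }
  num <- lapply(need, function(cn) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(df[[cn]]))
    if (length(bad)) {
      stop_wallmech("wallmech_parse",
                    sprintf("non-numeric value in column '%s', row %d: '%s'",
                            cn, bad[1], df[[cn]][bad[1]]))
    }
    v
  })
  names(num) <- need
  if ("segment" %in% names(df)) {
    parts <- strsplit(df$segment, ":", fixed = TRUE)
    ok <- lengths(parts) == 2
    if (!all(ok)) {
      stop_wallmech("wallmech_parse",
                    sprintf("malformed segment label in row %d: '%s'",
                            which(!ok)[1], df$segment[which(!ok)[1]]))
    }
    cycle <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    phase <- vapply(parts, `[`, "", 2)
    if (anyNA(cycle) || !all(phase %in% c("loading", "unloading"))) {
      stop_wallmech("wallmech_parse",
                    "segment labels must be '<cycle>:loading|unloading'")
    }
    tensile_curve(num$time_s, num$lambda_ax, num$lambda_tr,
                  num$force_per_width_N_per_m, cycle = cycle, phase = phase)
  } else {
    tensile_curve(num$time_s, num$lambda_ax, num$lambda_tr,
                  num$force_per_width_N_per_m)
  }
}

#' Write a tensile curve to CSV
#'
#' Writes the standard curve dialect with 9 significant digits (values
#' round-trip through [read_curve_csv()] within float precision).
#'
#' @param curve a `tensile_curve` or `cyclic_curve`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  fmt <- function(x) formatC(x, digits = 9, format = "g")
  df <- data.frame(time_s = fmt(curve$time_s),
                   lambda_ax = fmt(curve$lambda_ax),
                   lambda_tr = fmt(curve$lambda_tr),
                   force_per_width_N_per_m = fmt(curve$force_per_width))
  if (!is.null(curve$cycle)) {
    df$segment <- paste0(curve$cycle, ":", curve$phase)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the standard output bundle of an analysis run
#'
#' Writes the curve CSV, a summary JSON with stable key order (E1, E2,
#' nu1, nu2, regime bounds, maximum stretch, optional per-cycle recovery
#' table) and a small run log recording the configuration, seed and
#' package version.
#'
#' @param curve a `tensile_curve`/`cyclic_curve`, or `NULL`.
#' @param summary a `mech_summary`, or `NULL`.
#' @param path_prefix path prefix; files `<prefix>_curve.csv`,
#'   `<prefix>_summary.json`, `<prefix>_log.json` are produced.
#' @param recovery optional `recovery_result` to embed in the summary.
#' @param config optional configuration list echoed into the log.
#' @param seed optional seed echoed into the log.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(curve = NULL, summary = NULL, path_prefix,
                          recovery = NULL, config = NULL, seed = NULL) {
  written <- character(0)
  if (!is.null(curve)) {
    p <- paste0(path_prefix, "_curve.csv")
    write_curve_csv(curve, p)
    written <- c(written, p)
  }
  if (!is.null(summary) || !is.null(recovery)) {
    obj <- list()
    if (!is.null(summary)) {
      obj <- list(E1 = summary$E1, E2 = summary$E2,
                  nu1 = summary$nu1, nu2 = summary$nu2,
                  regime_bounds = summary$regime_bounds,
                  lambda_max = summary$lambda_max)
    }
    if (!is.null(recovery)) {
      obj$recovery <- as.data.frame(recovery)
    }
    p <- paste0(path_prefix, "_summary.json")
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = 9, pretty = TRUE)
    written <- c(written, p)
  }
  p <- paste0(path_prefix, "_log.json")
  jsonlite::write_json(
    list(package = "wallmech",
         version = as.character(utils::packageVersion("wallmech")),
         seed = seed, config = config,
         written = as.list(written)),
    p, auto_unbox = TRUE, pretty = TRUE, null = "null")
  written <- c(written, p)
  invisible(written)
}

#' Read and validate a run configuration
#'
#' Configurations are JSON (or YAML when the `yaml` package is
#' installed) with parameter blocks named after the model they
#' configure: `affine`, `five_beam`, `plate`, `shell`, `generator`,
#' `analysis`, plus `io`, `seed` and `log_level`. Unknown top-level keys
#' are rejected; each block is validated by the corresponding
#' constructor before any computation, so invalid physical parameters
#' fail fast. Angles are given in degrees; stretch grids as
#' `(start, stop, n)`.
#'
#' @param path configuration file path (`.json`, `.yaml`, `.yml`).
#' @return Named list with validated parameter objects in place of the
#'   raw blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_wallmech("wallmech_io", paste0("file not found: ", path))
  }
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_wallmech("wallmech_io", "YAML config needs the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("affine", "five_beam", "plate", "generator", "shell",
             "analysis", "io", "seed", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_wallmech("wallmech_schema",
                  paste0("unknown config key(s): ",
                         paste(unknown, collapse = ", ")))
  }
  out <- raw
  if (!is.null(raw$affine)) {
    out$affine <- do.call(affine_params, raw$affine)
  }
  if (!is.null(raw$five_beam)) {
    out$five_beam <- do.call(five_beam_params, raw$five_beam)
  }
  if (!is.null(raw$plate)) out$plate <- do.call(hyperelastic_material, raw$plate)
  if (!is.null(raw$generator)) {
    out$generator <- do.call(generator_profile, raw$generator)
  }
  out
}
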