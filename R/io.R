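#' Read a time series from CSV
#'
#' Expects a header and two numeric columns, time then value (any column
#' names are accepted; extra columns are ignored with a warning).
#' Validation rejects non-numeric cells, missing values and duplicated
#' time stamps, naming the offending lines. Non-uniform time grids are
#' loaded but flagged, since the likelihood machinery assumes an equally
#' spaced grid (noise parameters are defined per sampling interval).
#'
#' @param path CSV file path.
#' @return A tibble with columns `time` and `value` and attribute
#'   `uniform` (`TRUE` when max relative deviation of the spacing is
#'   below 1e-9).
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2) stop("Expected two columns (time, value) in ", path, call. = FALSE)
  if (ncol(raw) > 2) warning("Extra columns ignored in ", path, call. = FALSE)
  time <- suppressWarnings(as.numeric(raw[[1]]))
  value <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(time) | is.na(value))
  if (length(bad) > 0) {
    stop("Non-numeric or missing entries at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  dup <- which(duplicated(time))
  if (length(dup) > 0) {
    stop("Duplicated time stamp at line(s): ",
         paste(utils::head(dup + 1L, 5), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  ord <- order(time)
  out <- tibble::tibble(time = time[ord], value = value[ord])
  attr(out, "uniform") <- is_uniform_grid(out$time)
  out
}

is_uniform_grid <- function(times) {
  if (length(times) < 3) return(TRUE)
  d <- diff(times)
  max(abs(d - mean(d))) / mean(abs(d)) < 1e-9
}

#' Write a time series to CSV
#'
#' Writes `time` and `value` columns at 17 significant digits, so that a
#' read/write round trip is lossless for doubles.
#'
#' @param x Data frame with `time` and `value` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path) {
  stopifnot(all(c("time", "value") %in% names(x)))
  df <- data.frame(
    time = formatC(x$time, digits = 17, format = "g"),
    value = formatC(x$value, digits = 17, format = "g")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an error series to CSV
#'
#' Single `value` column with header, as produced by [simulate_arma()].
#'
#' @param x A [simulate_arma()] result (or numeric vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_error_series_csv <- function(x, path) {
  value <- as_values(x)
  utils::write.csv(
    data.frame(value = formatC(value, digits = 17, format = "g")),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and validate a run configuration
#'
#' JSON configuration with sections `model` (name + parameters), `noise`
#' (a [noise_spec()] schema plus `"noise_model"`:
#' `"iid" | "ar1" | "arma11" | "arma_kalman"`), `inference` (mode, chains,
#' iterations, seed) and `io` (paths). Unknown keys are rejected before
#' any computation.
#'
#' @param path JSON file path.
#' @return A validated list of class `odn_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("model", "noise", "inference", "io")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("Unknown config section(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg$model)) {
    unknown <- setdiff(names(cfg$model), c("name", "parameters", "priors"))
    if (length(unknown) > 0) stop("Unknown model key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    if (!cfg$model$name %in% c("constant", "logistic", "herg")) {
      stop("Unknown model name: ", cfg$model$name, call. = FALSE)
    }
  }
  if (!is.null(cfg$noise)) {
    unknown <- setdiff(names(cfg$noise), c("ar", "ma", "sigma", "d", "noise_model"))
    if (length(unknown) > 0) stop("Unknown noise key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    nm <- cfg$noise$noise_model %||% "iid"
    if (!nm %in% c("iid", "ar1", "arma11", "arma_kalman")) {
      stop("Unknown noise_model: ", nm, call. = FALSE)
    }
  }
  if (!is.null(cfg$inference)) {
    unknown <- setdiff(names(cfg$inference),
                       c("mode", "chains", "iterations", "warmup", "seed", "restarts"))
    if (length(unknown) > 0) stop("Unknown inference key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "odn_config")
}

config_model <- function(cfg) {
  switch(cfg$model$name,
         constant = constant_model(),
         logistic = logistic_model(),
         herg = herg_model(),
         stop("Unknown model name: ", cfg$model$name, call. = FALSE))
}

# Provenance record written next to every CLI artifact: enough to rerun
# the command identically.
write_provenance <- function(path, argv, seed = NULL, config = NULL) {
  prov <- list(
    package = "odenoise",
    version = as.character(utils::packageVersion("odenoise")),
    argv = argv,
    seed = seed,
    config_hash = if (is.null(config)) NULL else rlang::hash(config),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(prov, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
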