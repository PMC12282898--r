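#' Read a delimited time-series file
#'
#' CSV with a header whose first column is `time` followed by one or more
#' value columns.  Time must be strictly increasing; malformed input errors
#' with the offending line number.
#'
#' @param path File path.
#' @return A data frame (`biolum_series` when there is a single value
#'   column).
#' @export
read_timeseries <- function(path) {
  stopifnot(file.exists(path))
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  if (!identical(names(header)[1], "time")) {
    stop(sprintf("%s: expected a header starting with 'time', found '%s'",
                 path, paste(names(header), collapse = ",")), call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                   path, cn, bad + 1L), call. = FALSE)
    }
  }
  if (any(diff(df$time) <= 0)) {
    bad <- which(diff(df$time) <= 0)[1]
    stop(sprintf("%s: time not strictly increasing at line %d",
                 path, bad + 2L), call. = FALSE)
  }
  if (ncol(df) == 2L && identical(names(df), c("time", "value"))) {
    return(biolum_series(df$time, df$value))
  }
  df
}

#' Write a time series to CSV
#'
#' Values are written with 12 significant digits, which round-trips exactly
#' through [read_timeseries()] for the dynamic ranges arising here.
#'
#' @param x A data frame with a `time` column, a [biolum_series()], or a
#'   [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  if (inherits(x, "trajectory")) x <- as.data.frame(x)
  stopifnot(is.data.frame(x), "time" %in% names(x))
  out <- as.data.frame(lapply(x, function(col) {
    if (is.numeric(col)) formatC(col, format = "g", digits = 12) else col
  }))
  names(out) <- names(x)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a structured parameter configuration
#'
#' JSON (or YAML when the `yaml` package is available) with blocks keyed by
#' object type, e.g.
#' `{"goodwin": {"k1": 1, ..., "transcription": {"form": "power_law",
#' "r": 1, "n": 10}}, "forcing": {"I": 0.01, "Omega": 1.7}}`.
#'
#' @param path File path (`.json`, `.yml`, or `.yaml`).
#' @return Named list of constructed parameter objects (`goodwin`,
#'   `forcing`, `arrhenius` as present).
#' @export
read_params_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- list()
  if (!is.null(cfg$goodwin)) {
    g <- cfg$goodwin
    tr <- g$transcription
    out$goodwin <- goodwin_params(g$k1, g$k2, g$k3, g$p1, g$p2,
                                  transcription_spec(tr$form, r = tr$r,
                                                     n = tr$n, K = tr$K))
  }
  if (!is.null(cfg$forcing)) {
    out$forcing <- forcing_spec(cfg$forcing$I, cfg$forcing$Omega)
  }
  if (!is.null(cfg$arrhenius)) {
    a <- cfg$arrhenius
    out$arrhenius <- arrhenius_spec(unlist(a$A), unlist(a$E),
                                    R = if (is.null(a$R)) 8.314 else a$R)
  }
  out
}
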