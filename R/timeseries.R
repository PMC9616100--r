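#' Time-series container
#'
#' A minimal container for one observable channel sampled on a strictly
#' increasing time grid, with an optional per-point noise scale and free-form
#' metadata (ligand concentration, enzyme concentration, variant, ...).  For
#' 1D NMR spectra the "time" axis holds the frequency axis instead; the
#' monotonicity contract is the same.
#'
#' @param times strictly increasing numeric vector (seconds, or ppm for
#'   frequency-domain traces).
#' @param values finite numeric vector, same length as `times`.
#' @param sigma optional positive noise scale, scalar or per point.
#' @param meta named list of labels.
#' @export
kk_timeseries <- function(times, values, sigma = NULL, meta = list()) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop(sprintf("times must be strictly increasing (violated at row %d)",
                 bad[1] + 1L))
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (any(sigma <= 0)) stop("sigma must be > 0 when present")
    if (!length(sigma) %in% c(1L, length(times)))
      stop("sigma must be scalar or per-point")
  }
  structure(list(times = times, values = values, sigma = sigma, meta = meta),
            class = "kk_timeseries")
}

#' @export
print.kk_timeseries <- function(x, ...) {
  cat(sprintf("<kk_timeseries: %d points, t in [%g, %g]>\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  if (length(x$meta))
    cat("meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a two-column time-series CSV
#'
#' Expects a header and two numeric columns (time, signal), "." decimal,
#' comma separated, UTF-8.  Non-monotone time stamps and locale-style comma
#' decimals are rejected with the offending row identified.
#'
#' @param path file path.
#' @return a [kk_timeseries()].
#' @export
load_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE)
  if (ncol(df) < 2L) stop("expected a two-column CSV with header: ", path)
  parse_num <- function(x, col) {
    n <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(n) & nzchar(trimws(x)))
    if (length(bad)) {
      hint <- if (any(grepl(",", x[bad]))) " (comma decimal separator? use '.')" else ""
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d%s",
                   x[bad[1]], col, bad[1], hint))
    }
    n
  }
  times <- parse_num(df[[1]], names(df)[1])
  values <- parse_num(df[[2]], names(df)[2])
  bad <- which(diff(times) <= 0)
  if (length(bad))
    stop(sprintf("times not strictly increasing at data row %d in %s",
                 bad[1] + 1L, path))
  kk_timeseries(times, values)
}

#' Write a time series as a two-column CSV
#' @param ts a [kk_timeseries()].
#' @param path output path.
#' @param header column names, default `c("time_s", "signal")`.
#' @export
write_timeseries_csv <- function(ts, path, header = c("time_s", "signal")) {
  df <- data.frame(a = fmt_num(ts$times), b = fmt_num(ts$values))
  names(df) <- header
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed-format numbers so identical data give byte-identical files
fmt_num <- function(x) trimws(formatC(x, format = "g", digits = 15))

#' Export a trajectory as CSV ("time_s,<species...>")
#' @param traj data.frame from [integrate_scheme()].
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(lapply(traj, fmt_num))
  names(df) <- names(traj)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
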