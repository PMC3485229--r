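#' Time-intensity trace
#'
#' A single pixel's (or ROI's) fluorescence time series on a uniform time
#' grid. All kinetic analysis operates on this container, either on the
#' native camera grid (one sample per frame) or on the interpolated grid.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   and uniformly spaced (to within 1e-9 relative tolerance).
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `t`.
#' @return An object of class `cbf_trace`: a list with elements `t`,
#'   `intensity` and the time step `dt` (seconds).
#' @examples
#' tr <- cbf_trace(seq(0, 22.62, by = 0.58), rnorm(40, 100, 1))
#' tr$dt
#' @export
cbf_trace <- function(t, intensity) {
  if (!is.numeric(t) || !is.numeric(intensity)) {
    stop("`t` and `intensity` must be numeric vectors", call. = FALSE)
  }
  if (length(t) != length(intensity)) {
    stop("`t` and `intensity` must have the same length", call. = FALSE)
  }
  n <- length(t)
  if (n < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  dt <- (t[n] - t[1]) / (n - 1)
  if (dt <= 0) stop("`t` must be strictly increasing", call. = FALSE)
  if (max(abs(diff(t) - dt)) > 1e-9 * max(dt, 1)) {
    stop("`t` must be uniformly spaced", call. = FALSE)
  }
  structure(
    list(t = as.numeric(t), intensity = as.numeric(intensity), dt = dt),
    class = "cbf_trace"
  )
}

#' @export
print.cbf_trace <- function(x, ...) {
  cat(sprintf(
    "<cbf_trace> %d samples, dt = %.4g s, t = [%.4g, %.4g] s, I = [%.4g, %.4g]\n",
    length(x$t), x$dt, x$t[1], x$t[length(x$t)],
    min(x$intensity), max(x$intensity)
  ))
  invisible(x)
}

#' @export
length.cbf_trace <- function(x) length(x$t)

#' Read and write two-column trace files
#'
#' Delimited text with a header row and two columns, time in seconds and
#' intensity in arbitrary units.
#'
#' @param path File path.
#' @return `read_trace_csv()` returns a [cbf_trace]; `write_trace_csv()`
#'   returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected two columns (t, intensity)", call. = FALSE)
  cbf_trace(df[[1]], df[[2]])
}

#' @rdname read_trace_csv
#' @param trace A [cbf_trace].
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(t = trace$t, intensity = trace$intensity)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
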