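# Preprocessing: analysis-window selection, Savitzky-Golay smoothing,
# cubic-spline upsampling, baseline estimation and the per-pixel QC mask.

#' Restrict a stack to the initial analysis window
#'
#' Map generation uses only the first-pass portion of the acquisition; by
#' default the initial 40 frames (23.2 s at the default 0.58 s frame
#' interval) are retained.
#'
#' @param stack An [acq_stack].
#' @param n_frames Number of leading frames to keep (default 40). If the
#'   stack is shorter, all frames are kept with a warning.
#' @return An [acq_stack] with at most `n_frames` frames.
#' @export
select_analysis_window <- function(stack, n_frames = 40) {
  stopifnot(inherits(stack, "acq_stack"))
  if (!is.numeric(n_frames) || length(n_frames) != 1 || n_frames < 2) {
    stop("`n_frames` must be a single number >= 2", call. = FALSE)
  }
  n_frames <- as.integer(n_frames)
  total <- dim(stack$frames)[1]
  if (total < n_frames) {
    warning(sprintf("stack has only %d frames; requested %d", total, n_frames),
            call. = FALSE)
    return(stack)
  }
  out <- stack
  out$frames <- stack$frames[seq_len(n_frames), , , drop = FALSE]
  out
}

# Least-squares polynomial fit weights: value of the degree-`order` fit at
# offset 0, for samples at the given integer offsets.
sg_weights <- function(offsets, order) {
  X <- outer(offsets, 0:order, `^`)
  solve(crossprod(X), t(X))[1L, ]
}

#' Savitzky-Golay smoothing of a trace
#'
#' Each output sample is the value, at the window centre, of the local
#' least-squares polynomial fit of degree `order` over `window` consecutive
#' samples. Near the trace ends the window shrinks symmetrically; where
#' fewer than `order + 2` points would remain, the fit uses the nearest
#' `order + 2` points and is evaluated at the output position.
#'
#' @param trace A [cbf_trace].
#' @param window Odd window length in samples (default 7).
#' @param order Polynomial order (default 3).
#' @return A smoothed [cbf_trace] on the same time grid.
#' @export
smooth_trace <- function(trace, window = 7, order = 3) {
  stopifnot(inherits(trace, "cbf_trace"))
  n <- length(trace$t)
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  if (window <= order) stop("`window` must exceed `order`", call. = FALSE)
  if (window > n) stop("`window` exceeds the trace length", call. = FALSE)
  if (n < order + 2) stop("trace too short for the requested order", call. = FALSE)

  h <- (window - 1L) / 2L
  y <- trace$intensity
  out <- numeric(n)
  wcache <- list()
  min_pts <- order + 2L
  for (i in seq_len(n)) {
    hs <- min(h, i - 1L, n - i)
    if (2L * hs + 1L >= min_pts) {
      key <- sprintf("s%d", hs)
      if (is.null(wcache[[key]])) wcache[[key]] <- sg_weights(-hs:hs, order)
      out[i] <- sum(wcache[[key]] * y[(i - hs):(i + hs)])
    } else if (i <= n / 2) {
      idx <- seq_len(min_pts)
      out[i] <- sum(sg_weights(idx - i, order) * y[idx])
    } else {
      idx <- (n - min_pts + 1L):n
      out[i] <- sum(sg_weights(idx - i, order) * y[idx])
    }
  }
  cbf_trace(trace$t, out)
}

#' Upsample a trace with a natural cubic spline
#'
#' Interpolates the trace onto a uniform grid from its first to (at most)
#' its last sample with step `dt_out`. The interpolant passes through every
#' original sample; the boundary condition is natural (zero second
#' derivative at the ends).
#'
#' @param trace A [cbf_trace].
#' @param dt_out Output time step in seconds; must be positive and no
#'   larger than the native step. Default 0.0116 s (i.e. 1/50 of the
#'   default 0.58 s frame interval).
#' @return An interpolated [cbf_trace].
#' @export
interpolate_trace <- function(trace, dt_out = 0.0116) {
  stopifnot(inherits(trace, "cbf_trace"))
  if (!is.numeric(dt_out) || length(dt_out) != 1 || dt_out <= 0) {
    stop("`dt_out` must be a single positive number", call. = FALSE)
  }
  if (dt_out > trace$dt * (1 + 1e-9)) {
    stop("`dt_out` must not exceed the native time step", call. = FALSE)
  }
  n <- length(trace$t)
  span <- trace$t[n] - trace$t[1]
  m <- floor(span / dt_out + 1e-9)
  t_out <- trace$t[1] + (0:m) * dt_out
  sf <- stats::splinefun(trace$t, trace$intensity, method = "natural")
  cbf_trace(t_out, sf(t_out))
}

#' Baseline (pre-arrival) intensity of a trace
#'
#' The baseline is the mean intensity over the samples strictly before the
#' bolus arrival time when at least three such samples exist; otherwise it
#' falls back to the minimum intensity of the trace (with a warning when an
#' arrival time had been supplied). Subtracting it defines the
#' baseline-zeroed trace on which the mean transit time is computed.
#'
#' @param trace A [cbf_trace].
#' @param t_arrival Optional bolus arrival time in seconds.
#' @return The baseline intensity (scalar).
#' @export
estimate_baseline <- function(trace, t_arrival = NULL) {
  stopifnot(inherits(trace, "cbf_trace"))
  if (!is.null(t_arrival)) {
    pre <- trace$intensity[trace$t < t_arrival - 1e-12]
    if (length(pre) >= 3) return(mean(pre))
    warning("fewer than 3 pre-arrival samples; falling back to the minimum rule",
            call. = FALSE)
  }
  min(trace$intensity)
}

#' Per-pixel signal-quality mask
#'
#' A pixel passes QC when its smoothed bolus amplitude (maximum of the
#' smoothed series minus its pre-peak baseline, the mean of the smoothed
#' values over the noise window) is at least `snr_threshold` times a
#' robust noise scale, estimated as 1.4826 times the median absolute
#' deviation of the raw-minus-smoothed residuals over the noise window.
#' The noise window is the pre-peak frames excluding the smoother's
#' half-width just before the peak (where least-squares bias on the steep
#' rise would masquerade as noise); when fewer than 12 frames qualify,
#' all frames are used so the estimate stays stable. On a noiseless bolus
#' the window is flat, the residuals vanish and the pixel passes at any
#' finite threshold. Pixels that fail carry no kinetic parameters
#' downstream.
#'
#' @param stack An [acq_stack] (typically already restricted to the
#'   analysis window).
#' @param snr_threshold Amplitude-to-noise ratio required to pass
#'   (default 5).
#' @param window,order Savitzky-Golay settings used for the smoothed
#'   reference series (defaults 7 and 3).
#' @return A logical rows x cols matrix, `TRUE` where the pixel passes.
#'   Attributes `amplitude` and `noise` hold the per-pixel values used.
#' @export
qc_mask <- function(stack, snr_threshold = 5, window = 7, order = 3) {
  stopifnot(inherits(stack, "acq_stack"))
  d <- dim(stack$frames)
  nt <- d[1]; nr <- d[2]; nc <- d[3]
  y <- matrix(stack$frames, nrow = nt)           # frames x pixels
  S <- smoothing_operator(nt, stack$frame_interval, window, order)
  sm <- S %*% y
  amp <- numeric(ncol(y)); noise <- numeric(ncol(y))
  half <- (window - 1L) %/% 2L
  for (p in seq_len(ncol(y))) {
    s <- sm[, p]
    pk <- which.max(s)
    pre <- if (pk - 1L - half >= 8L) seq_len(pk - 1L - half) else seq_len(nt)
    noise[p] <- stats::mad(y[pre, p] - s[pre])
    amp[p] <- max(s) - mean(s[pre])
  }
  mask <- matrix(amp >= snr_threshold * noise, nr, nc)
  attr(mask, "amplitude") <- matrix(amp, nr, nc)
  attr(mask, "noise") <- matrix(noise, nr, nc)
  mask
}

# Smoothing as an explicit linear operator (n x n), columns = smoothed unit
# impulses. Used to smooth many pixels at once with one matrix product;
# identical by construction to smooth_trace() on each series.
smoothing_operator <- function(n, dt, window = 7, order = 3) {
  tt <- (seq_len(n) - 1) * dt
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    S[, j] <- smooth_trace(cbf_trace(tt, e), window, order)$intensity
  }
  S
}
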