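# Kinetic parameter extraction from a processed time-intensity curve:
# half-intensity anchor, backward/forward tracing to the bolus arrival and
# first peak, rising time, windowed mean transit time and blood flow index.

#' Half-intensity time of a trace
#'
#' The anchor of the tracing algorithm: the earliest time at which the
#' intensity is equal to or greater than the median intensity over the
#' analysis window. For even-length windows the median is the mean of the
#' two central order statistics.
#'
#' @param trace A smoothed, interpolated [cbf_trace] restricted to the
#'   analysis window.
#' @return The half-intensity time in seconds (the sample index is
#'   attached as attribute `index`).
#' @export
find_t_half <- function(trace) {
  stopifnot(inherits(trace, "cbf_trace"))
  y <- trace$intensity
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1)) {
    stop_kinetics("flat", "flat trace: the median equals every value")
  }
  med <- stats::median(y)
  idx <- which(y >= med)[1]
  structure(trace$t[idx], index = idx)
}

#' Trace backward from the half-intensity time to the bolus arrival
#'
#' Starting at the sample at `t_half`, steps backward in time while each
#' earlier sample is strictly lower than the current one; the last sample
#' reached is the arrival point.
#'
#' @param trace A processed [cbf_trace].
#' @param t_half Half-intensity time (seconds), as returned by
#'   [find_t_half()].
#' @return A list with `t_arrival` (s), `i_arrival` (intensity) and the
#'   sample `index`.
#' @export
trace_to_arrival <- function(trace, t_half) {
  stopifnot(inherits(trace, "cbf_trace"))
  i0 <- trace_index(trace, t_half)
  if (i0 == 1L) {
    warning("half-intensity time at the first sample; arrival set to it",
            call. = FALSE)
  }
  y <- trace$intensity
  j <- i0
  while (j > 1L && y[j - 1L] < y[j]) j <- j - 1L
  list(t_arrival = trace$t[j], i_arrival = y[j], index = j)
}

#' Trace forward from the half-intensity time to the first peak
#'
#' Starting at the sample at `t_half`, steps forward in time while each
#' later sample is strictly higher than the current one; the last sample
#' reached is the first peak. This is the first local maximum of the
#' curve, not the global maximum: recirculation can produce later, larger
#' peaks (as it does over skeletal muscle), which are reported separately
#' as `t_max`/`i_max`.
#'
#' @inheritParams trace_to_arrival
#' @return A list with `t_peak` (s), `i_peak` (intensity) and the sample
#'   `index`.
#' @export
trace_to_peak <- function(trace, t_half) {
  stopifnot(inherits(trace, "cbf_trace"))
  i0 <- trace_index(trace, t_half)
  n <- length(trace$t)
  if (i0 == n) {
    stop_kinetics("truncated peak",
                  "half-intensity time at the last sample; first peak not covered")
  }
  y <- trace$intensity
  j <- i0
  while (j < n && y[j + 1L] > y[j]) j <- j + 1L
  if (j == n) {
    warning("intensity still rising at the end of the window; peak may be truncated",
            call. = FALSE)
  }
  list(t_peak = trace$t[j], i_peak = y[j], index = j)
}

trace_index <- function(trace, t) {
  idx <- attr(t, "index")
  if (!is.null(idx)) return(idx)
  which.min(abs(trace$t - as.numeric(t)))
}

#' Rising time of the first pass
#'
#' The time taken to reach the first peak after arrival of the bolus.
#'
#' @param t_arrival,t_peak Arrival and first-peak times in seconds.
#' @return `t_peak - t_arrival` in seconds.
#' @export
rising_time <- function(t_arrival, t_peak) {
  d <- t_peak - t_arrival
  if (d < 0) stop_kinetics("negative rise", "t_peak precedes t_arrival")
  d
}

#' Mean transit time over a fixed post-arrival window
#'
#' The centre of gravity of the baseline-zeroed dynamic curve over the
#' `window` seconds following the bolus arrival:
#' `MTT = integral(tau * I(t_arrival + tau)) / integral(I(t_arrival + tau))`
#' for `tau` in `[0, window]`, where `tau` is time since arrival. Both
#' integrals use trapezoidal quadrature on the trace's grid. No arterial
#' input deconvolution is applied, so the value is a relative (not
#' absolute) transit time, suitable for within-image comparisons.
#'
#' @param trace A baseline-zeroed, processed [cbf_trace].
#' @param t_arrival Bolus arrival time in seconds.
#' @param window Integration window in seconds after arrival (default
#'   20 s). If the trace ends earlier the window is clipped with a
#'   warning.
#' @return The mean transit time in seconds, relative to `t_arrival`.
#' @export
mean_transit_time <- function(trace, t_arrival, window = 20) {
  stopifnot(inherits(trace, "cbf_trace"))
  if (!is.numeric(window) || window <= 0) {
    stop("`window` must be a positive duration in seconds", call. = FALSE)
  }
  t_end <- trace$t[length(trace$t)]
  if (t_end < t_arrival + window - 1e-9) {
    warning(sprintf(
      "trace ends %.3g s after arrival; MTT window clipped from %.3g s",
      t_end - t_arrival, window), call. = FALSE)
  }
  keep <- trace$t >= t_arrival - 1e-12 & trace$t <= t_arrival + window + 1e-12
  if (sum(keep) < 2) stop_kinetics("no mass", "no samples in the MTT window")
  tau <- trace$t[keep] - t_arrival
  y <- trace$intensity[keep]
  den <- pracma::trapz(tau, y)
  if (!is.finite(den) || den <= 0) {
    stop_kinetics("no mass", "nonpositive integral of the baseline-zeroed curve")
  }
  pracma::trapz(tau, tau * y) / den
}

#' Blood flow index
#'
#' The slope of the first peak of the time-intensity curve:
#' `(i_peak - i_arrival) / t_rising`, in intensity units per second. The
#' index combines timing and volume information; its scale depends on the
#' injected dye amount, so it supports relative comparisons only.
#'
#' @param i_arrival,i_peak Intensities at arrival and at the first peak.
#' @param t_rising Rising time in seconds; must be positive.
#' @return The blood flow index (intensity per second).
#' @export
blood_flow_index <- function(i_arrival, i_peak, t_rising) {
  if (t_rising <= 0) stop_kinetics("zero rise", "rising time is not positive")
  (i_peak - i_arrival) / t_rising
}

#' Full kinetic analysis of one trace
#'
#' Runs the whole per-pixel chain: Savitzky-Golay smoothing, cubic-spline
#' interpolation, half-intensity anchoring, backward/forward tracing to
#' arrival and first peak, baseline estimation, windowed mean transit time
#' and blood flow index. The global maximum (`t_max`, `i_max`) is recorded
#' alongside the first-peak values. Any stage failure yields an invalid
#' record with a reason code rather than an error.
#'
#' @param trace A [cbf_trace], raw (native camera grid) or already
#'   processed.
#' @param config A [cbf_config] with the analysis settings.
#' @param preprocessed Set `TRUE` when `trace` is already smoothed and
#'   interpolated (smoothing and interpolation are then skipped).
#' @return A `kinetic_params` record: a list with fields `t_half`,
#'   `t_arrival`, `t_peak`, `t_rising`, `i_arrival`, `i_peak`, `t_max`,
#'   `i_max`, `mtt`, `bfi`, `baseline`, `valid`, `reason` and `notes`
#'   (collected warnings).
#' @export
analyze_trace <- function(trace, config = cbf_config(), preprocessed = FALSE) {
  stopifnot(inherits(trace, "cbf_trace"))
  notes <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  run <- function() {
    proc <- trace
    if (!preprocessed) {
      proc <- smooth_trace(proc, config$smoothing_window, config$smoothing_order)
      proc <- interpolate_trace(proc, config$interp_dt)
    }
    th <- find_t_half(proc)
    arr <- trace_to_arrival(proc, th)
    pk <- trace_to_peak(proc, th)
    t_rising <- rising_time(arr$t_arrival, pk$t_peak)
    baseline <- estimate_baseline(proc, arr$t_arrival)
    zeroed <- cbf_trace(proc$t, proc$intensity - baseline)
    mtt <- mean_transit_time(zeroed, arr$t_arrival, config$mtt_window)
    bfi <- blood_flow_index(arr$i_arrival, pk$i_peak, t_rising)
    imax <- which.max(proc$intensity)
    kinetic_params(
      t_half = as.numeric(th), t_arrival = arr$t_arrival, t_peak = pk$t_peak,
      t_rising = t_rising, i_arrival = arr$i_arrival, i_peak = pk$i_peak,
      t_max = proc$t[imax], i_max = proc$intensity[imax],
      mtt = mtt, bfi = bfi, baseline = baseline,
      valid = TRUE, reason = NA_character_, notes = notes
    )
  }
  tryCatch(
    collect(run()),
    cbf_kinetics_error = function(e) {
      kinetic_params(valid = FALSE, reason = kinetics_reason(e),
                     notes = c(notes, conditionMessage(e)))
    }
  )
}

kinetic_params <- function(t_half = NA_real_, t_arrival = NA_real_,
                           t_peak = NA_real_, t_rising = NA_real_,
                           i_arrival = NA_real_, i_peak = NA_real_,
                           t_max = NA_real_, i_max = NA_real_,
                           mtt = NA_real_, bfi = NA_real_,
                           baseline = NA_real_, valid = FALSE,
                           reason = NA_character_, notes = character()) {
  structure(
    list(t_half = t_half, t_arrival = t_arrival, t_peak = t_peak,
         t_rising = t_rising, i_arrival = i_arrival, i_peak = i_peak,
         t_max = t_max, i_max = i_max, mtt = mtt, bfi = bfi,
         baseline = baseline, valid = valid, reason = reason, notes = notes),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<kinetic_params> invalid (%s)\n", x$reason))
    return(invisible(x))
  }
  cat("<kinetic_params>\n")
  cat(sprintf("  t_arrival %.3f s   t_peak %.3f s   t_rising %.3f s\n",
              x$t_arrival, x$t_peak, x$t_rising))
  cat(sprintf("  MTT %.3f s   BFI %.4g /s   (t_half %.3f s, t_max %.3f s)\n",
              x$mtt, x$bfi, x$t_half, x$t_max))
  invisible(x)
}

#' @export
format.kinetic_params <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = TRUE)
}
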