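# Parametric map assembly: per-pixel kinetic analysis over the QC-passed
# pixels, display scaling, and BFI normalization.

#' Compute the four parametric CBF maps from a stack
#'
#' Restricts the stack to the analysis window, builds the QC mask, applies
#' [analyze_trace()] to every passing pixel and assembles the arrival-time,
#' rising-time, mean-transit-time and blood-flow-index maps. Pixels that
#' fail QC, or whose analysis returns an invalid record, hold `NA` and are
#' `FALSE` in the final mask. Each pixel is processed independently (no
#' spatial smoothing); the result is deterministic given stack and config.
#'
#' @param stack An [acq_stack].
#' @param config A [cbf_config].
#' @return An object of class `cbf_maps`: a list with matrices
#'   `t_arrival`, `t_rising`, `mtt`, `bfi` (plus `t_peak` and `t_max` for
#'   diagnostics), the logical `qc` mask, a table of failure `reasons`,
#'   and the `config` and stack metadata used.
#' @export
compute_maps <- function(stack, config = cbf_config()) {
  stopifnot(inherits(stack, "acq_stack"))
  win <- suppress_to_notes(select_analysis_window(stack, config$n_frames))
  stack_w <- win$value
  qc <- qc_mask(stack_w, snr_threshold = config$qc_snr_threshold,
                window = config$smoothing_window,
                order = config$smoothing_order)
  d <- dim(stack_w$frames)
  nr <- d[2]; nc <- d[3]
  tt <- (seq_len(d[1]) - 1) * stack_w$frame_interval
  blank <- matrix(NA_real_, nr, nc)
  maps <- list(t_arrival = blank, t_rising = blank, mtt = blank, bfi = blank,
               t_peak = blank, t_max = blank)
  valid <- matrix(FALSE, nr, nc)
  reasons <- character()
  for (idx in which(qc)) {
    row <- (idx - 1) %% nr + 1
    col <- (idx - 1) %/% nr + 1
    kp <- analyze_trace(cbf_trace(tt, stack_w$frames[, row, col]), config)
    if (kp$valid) {
      valid[idx] <- TRUE
      maps$t_arrival[idx] <- kp$t_arrival
      maps$t_rising[idx] <- kp$t_rising
      maps$mtt[idx] <- kp$mtt
      maps$bfi[idx] <- kp$bfi
      maps$t_peak[idx] <- kp$t_peak
      maps$t_max[idx] <- kp$t_max
    } else {
      reasons <- c(reasons, kp$reason)
    }
  }
  structure(
    list(t_arrival = maps$t_arrival, t_rising = maps$t_rising,
         mtt = maps$mtt, bfi = maps$bfi, t_peak = maps$t_peak,
         t_max = maps$t_max, qc = valid,
         n_qc_failed = sum(!qc), reasons = table(reasons),
         config = config, notes = win$notes,
         pixel_size = stack$pixel_size, bregma_px = stack$bregma_px,
         midline_col = stack$midline_col),
    class = "cbf_maps"
  )
}

suppress_to_notes <- function(expr) {
  notes <- character()
  value <- withCallingHandlers(expr, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = value, notes = notes)
}

#' @export
print.cbf_maps <- function(x, ...) {
  d <- dim(x$qc)
  cat(sprintf("<cbf_maps> %d x %d px, %d valid (%d QC-failed, %d invalid)\n",
              d[1], d[2], sum(x$qc), x$n_qc_failed, sum(x$reasons)))
  for (p in c("t_arrival", "t_rising", "mtt", "bfi")) {
    v <- x[[p]][x$qc]
    if (length(v)) {
      cat(sprintf("  %-9s [%.4g, %.4g]%s\n", p, min(v), max(v),
                  if (p == "bfi") " /s" else " s"))
    }
  }
  invisible(x)
}

#' Linear display scaling of a parameter map
#'
#' Maps `[lo, hi]` linearly onto gray levels 0..255, clipping values
#' outside the range. The automatic range is the 1st-99th percentile of
#' the valid pixels (robust to isolated hot pixels). Masked (`NA`) pixels
#' are rendered as gray 0; pair the image with the map's QC mask to
#' distinguish them from true low values. The range actually used is
#' returned for the map legend (seconds for the time parameters,
#' arbitrary units for BFI).
#'
#' @param map Numeric matrix with `NA` at masked pixels.
#' @param range Optional `c(lo, hi)`; `NULL` (default) selects the
#'   automatic percentile range.
#' @return A list of class `cbf_display` with the integer `image`
#'   (0..255) and the `range` used.
#' @export
scale_for_display <- function(map, range = NULL) {
  stopifnot(is.matrix(map))
  valid <- is.finite(map)
  if (!any(valid)) stop("no valid pixels to scale", call. = FALSE)
  degenerate <- FALSE
  if (is.null(range)) {
    range <- unname(stats::quantile(map[valid], c(0.01, 0.99)))
    if (range[1] >= range[2]) {
      warning("degenerate range: constant map rendered mid-gray", call. = FALSE)
      degenerate <- TRUE
    }
  } else {
    if (range[1] >= range[2]) stop("degenerate range: lo >= hi", call. = FALSE)
  }
  img <- matrix(0L, nrow(map), ncol(map))
  if (degenerate) {
    img[valid] <- 128L
  } else {
    v <- pmin(pmax(map[valid], range[1]), range[2])
    img[valid] <- as.integer(round(255 * (v - range[1]) / (range[2] - range[1])))
  }
  structure(list(image = img, range = range, mask_value = 0L),
            class = "cbf_display")
}

#' Normalize a BFI map
#'
#' In `"display"` mode the map is divided by its maximum over valid
#' pixels, giving values in (0, 1] for rendering; `"analysis"` mode
#' returns the map unchanged, since inter-hemisphere comparisons must use
#' the raw index.
#'
#' @param map Numeric BFI matrix with `NA` at masked pixels.
#' @param mode `"display"` or `"analysis"`.
#' @return A matrix of the same shape.
#' @export
normalize_bfi <- function(map, mode = c("display", "analysis")) {
  mode <- match.arg(mode)
  if (mode == "analysis") return(map)
  valid <- is.finite(map)
  if (!any(valid)) stop("no valid pixels in the BFI map", call. = FALSE)
  map / max(map[valid])
}
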