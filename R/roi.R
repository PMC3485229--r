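# Bregma-referenced ROI extraction, contralateral mirroring, per-ROI
# summaries and the two-group comparisons.
#
# Orientation convention (documented, since the raw images carry none):
# the animal is prone, viewed dorsally, anterior at the image top. Under
# that convention posterior offsets increase the row index and the
# animal's left is the image left, so a left-lateral offset decreases the
# column index.

#' Build a pixel ROI from millimetre offsets relative to bregma
#'
#' Converts `(anterior-posterior, medial-lateral)` millimetre offsets
#' (posterior and left-lateral positive) into a rectangular pixel
#' footprint. The footprint spans `ceiling(size_mm / pixel_size)` pixels
#' per axis, so a 2 mm ROI at 0.1 mm/pixel is exactly 20 pixels; when the
#' sub-pixel centre forces a half-pixel choice, the footprint is rounded
#' away from bregma so it always covers the nominal area.
#'
#' @param center_mm `c(posterior_mm, lateral_mm)` offsets of the ROI
#'   centre from bregma.
#' @param size_mm `c(height_mm, width_mm)` extent.
#' @param pixel_size mm per pixel.
#' @param bregma_px `(row, col)` pixel coordinate of bregma.
#' @param shape `(rows, cols)` of the image, for the bounds check.
#' @return An object of class `roi_spec` with integer vectors `rows` and
#'   `cols`.
#' @export
make_roi <- function(center_mm, size_mm = c(2, 2), pixel_size, bregma_px,
                     shape) {
  if (missing(pixel_size) || is.null(pixel_size) ||
      missing(bregma_px) || is.null(bregma_px)) {
    stop("`pixel_size` and `bregma_px` metadata are required", call. = FALSE)
  }
  stopifnot(length(center_mm) == 2, length(size_mm) == 2, all(size_mm > 0))
  n <- as.integer(ceiling(size_mm / pixel_size - 1e-9))
  centre <- c(bregma_px[1] + center_mm[1] / pixel_size,
              bregma_px[2] - center_mm[2] / pixel_size)
  first <- mapply(round_away, centre - (n - 1) / 2, bregma_px)
  rows <- first[1]:(first[1] + n[1] - 1L)
  cols <- first[2]:(first[2] + n[2] - 1L)
  if (!missing(shape)) {
    if (min(rows) < 1 || min(cols) < 1 || max(rows) > shape[1] ||
        max(cols) > shape[2]) {
      stop("ROI footprint extends outside the image", call. = FALSE)
    }
  }
  structure(list(rows = rows, cols = cols, center_mm = center_mm,
                 size_mm = size_mm, pixel_size = pixel_size,
                 bregma_px = bregma_px),
            class = "roi_spec")
}

# Round to the nearest integer; exact halves round away from the bregma
# coordinate so the footprint never shrinks toward the landmark.
round_away <- function(v, bregma) {
  f <- floor(v)
  if (abs(v - f - 0.5) < 1e-9) {
    if (v >= bregma) f + 1L else f
  } else {
    as.integer(round(v))
  }
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> rows %d..%d, cols %d..%d (%d px)\n",
              min(x$rows), max(x$rows), min(x$cols), max(x$cols),
              length(x$rows) * length(x$cols)))
  invisible(x)
}

#' Mirror an ROI across the sagittal midline
#'
#' Reflects the footprint's columns about `midline_col` (a pixel on the
#' midline maps to itself: `col -> 2 * midline_col - col`), preserving the
#' area exactly. Mirroring twice returns the original ROI.
#'
#' @param roi An [roi_spec].
#' @param midline_col Column index of the sagittal midline.
#' @param shape Optional `(rows, cols)` for the bounds check.
#' @return The mirrored `roi_spec`.
#' @export
mirror_roi <- function(roi, midline_col, shape) {
  stopifnot(inherits(roi, "roi_spec"))
  out <- roi
  out$cols <- sort(2L * as.integer(midline_col) - roi$cols)
  out$center_mm <- c(roi$center_mm[1], -roi$center_mm[2])
  if (!missing(shape) && (min(out$cols) < 1 || max(out$cols) > shape[2])) {
    stop("mirrored ROI extends outside the image", call. = FALSE)
  }
  out
}

#' Per-ROI parameter summaries
#'
#' For each of the four parameters: mean, standard error of the mean and
#' pixel counts over the QC-valid pixels of the footprint; masked pixels
#' are excluded and counted separately.
#'
#' @param maps A [compute_maps()] result.
#' @param roi An [roi_spec].
#' @param label Optional ROI label carried into the output.
#' @return A data frame with columns `roi`, `parameter`, `mean`, `sem`,
#'   `n_valid`, `n_masked`.
#' @export
roi_mean_params <- function(maps, roi, label = "roi") {
  stopifnot(inherits(maps, "cbf_maps"), inherits(roi, "roi_spec"))
  d <- dim(maps$qc)
  if (max(roi$rows) > d[1] || max(roi$cols) > d[2] ||
      min(roi$rows) < 1 || min(roi$cols) < 1) {
    stop("ROI outside map bounds", call. = FALSE)
  }
  ok <- maps$qc[roi$rows, roi$cols]
  if (!any(ok)) stop("ROI contains no QC-valid pixels", call. = FALSE)
  params <- c("t_arrival", "t_rising", "mtt", "bfi")
  do.call(rbind, lapply(params, function(p) {
    v <- maps[[p]][roi$rows, roi$cols][ok]
    data.frame(roi = label, parameter = p, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               n_valid = length(v), n_masked = sum(!ok))
  }))
}

#' Two-group comparison of parameter values
#'
#' Two-tailed Student t-test: unpaired (classical equal-variance by
#' default, Welch behind `var_equal = FALSE`) for independent groups, or
#' paired on the per-subject differences (the hemisphere comparison).
#' Degenerate inputs follow explicit conventions: identical constant
#' groups give `t = 0, p = 1`; a paired design with a constant nonzero
#' difference is reported as `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b Numeric value vectors (`n >= 2` each; equal lengths when
#'   paired).
#' @param paired Paired test on `a - b`?
#' @param var_equal Pool the variances (classical t)? Default `TRUE`.
#' @return A list with `statistic`, `df`, `p_value`, `method` and
#'   `degenerate`.
#' @export
compare_groups <- function(a, b, paired = FALSE, var_equal = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal-length groups", call. = FALSE)
  }
  method <- if (paired) "paired t-test" else if (var_equal)
    "two-sample t-test (pooled variance)" else "Welch two-sample t-test"
  if (paired) {
    d <- a - b
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        return(list(statistic = 0, df = length(d) - 1, p_value = 1,
                    method = method, degenerate = TRUE))
      }
      return(list(statistic = sign(mean(d)) * Inf, df = length(d) - 1,
                  p_value = 0, method = method, degenerate = TRUE))
    }
  } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1,
                  method = method, degenerate = TRUE))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_value = 0,
                method = method, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, method = method, degenerate = FALSE)
}
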