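# Acquisition stack container and TIFF I/O. Frames are stored as a
# (time x rows x cols) array in acquisition order; the coordinate
# convention is (row, col) with row 1 at the image top, matching TIFF
# order. Frame k (1-based) is at t = (k - 1) * frame_interval, i.e. t = 0
# at the first acquired frame.

#' Acquisition stack
#'
#' @param frames Numeric array `(time, rows, cols)` of intensities.
#' @param frame_interval Seconds per frame (> 0); required.
#' @param pixel_size mm per pixel (isotropic); required for ROI work.
#' @param bregma_px Optional `(row, col)` pixel coordinate of the bregma
#'   landmark.
#' @param midline_col Optional column index of the sagittal midline.
#' @param bit_depth Sensor bit depth; default 12 (values stored in 16-bit
#'   samples).
#' @param strict When `TRUE` (default), raw intensities outside
#'   `[0, 2^bit_depth - 1]` are an error; when `FALSE` they only warn.
#' @return An object of class `acq_stack`.
#' @export
acq_stack <- function(frames, frame_interval, pixel_size = NULL,
                      bregma_px = NULL, midline_col = NULL, bit_depth = 12,
                      strict = TRUE) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop("`frames` must be a (time x rows x cols) array", call. = FALSE)
  }
  if (dim(frames)[1] < 2) stop("a stack needs at least 2 frames", call. = FALSE)
  if (missing(frame_interval) || !is.numeric(frame_interval) ||
      length(frame_interval) != 1 || frame_interval <= 0) {
    stop("`frame_interval` (seconds per frame, > 0) is required", call. = FALSE)
  }
  if (!is.null(pixel_size) && pixel_size <= 0) {
    stop("`pixel_size` must be positive", call. = FALSE)
  }
  lim <- 2^bit_depth - 1
  if (min(frames) < 0 || max(frames) > lim) {
    msg <- sprintf("intensities outside [0, %d] for bit depth %d", lim, bit_depth)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size, bregma_px = bregma_px,
         midline_col = midline_col, bit_depth = bit_depth),
    class = "acq_stack"
  )
}

#' @export
print.acq_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<acq_stack> %d frames of %d x %d px, %.3g s/frame (%.3g s total), %d-bit\n",
    d[1], d[2], d[3], x$frame_interval, (d[1] - 1) * x$frame_interval,
    x$bit_depth))
  invisible(x)
}

#' Extract one pixel's trace from a stack
#'
#' @param stack An [acq_stack].
#' @param row,col Pixel coordinate (1-based, row 1 at the image top).
#' @return A [cbf_trace] on the native frame grid.
#' @export
pixel_trace <- function(stack, row, col) {
  stopifnot(inherits(stack, "acq_stack"))
  nt <- dim(stack$frames)[1]
  cbf_trace((seq_len(nt) - 1) * stack$frame_interval, stack$frames[, row, col])
}

#' Read an image stack from TIFF
#'
#' Accepts a multi-page grayscale TIFF or a directory of single-page TIFFs
#' in lexicographic frame order. Twelve-bit data stored in 16-bit samples
#' is read bit-exactly.
#'
#' @param path TIFF file or directory.
#' @param frame_interval Seconds per frame (required metadata).
#' @inheritParams acq_stack
#' @return An [acq_stack].
#' @export
read_stack <- function(path, frame_interval, pixel_size = NULL,
                       bregma_px = NULL, midline_col = NULL, bit_depth = 12,
                       strict = TRUE) {
  if (missing(frame_interval)) {
    stop("`frame_interval` (seconds per frame) is required", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF files in directory: ", path, call. = FALSE)
    unlist(lapply(files, tiff::readTIFF, all = TRUE, as.is = TRUE),
           recursive = FALSE)
  } else {
    tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  }
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("inconsistent frame shapes across TIFF pages", call. = FALSE)
  }
  nt <- length(pages)
  frames <- array(0, dim = c(nt, shapes[1, 1], shapes[2, 1]))
  for (k in seq_len(nt)) frames[k, , ] <- pages[[k]]
  acq_stack(frames, frame_interval = frame_interval, pixel_size = pixel_size,
            bregma_px = bregma_px, midline_col = midline_col,
            bit_depth = bit_depth, strict = strict)
}

#' Write an image stack to a multi-page 16-bit TIFF
#'
#' Integer intensities round-trip exactly through [read_stack()].
#'
#' @param stack An [acq_stack].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "acq_stack"))
  nt <- dim(stack$frames)[1]
  pages <- lapply(seq_len(nt), function(k) stack$frames[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}
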