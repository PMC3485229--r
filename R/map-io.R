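# Writing parameter maps (exact float text + 8-bit display PNGs + sidecar)
# and the ROI report.

#' Write a parameter map set to a directory
#'
#' Each of the four maps is written twice: as a plain-text float matrix
#' preserving the exact values (`<name>.txt`, `NA` at masked pixels) and
#' as an 8-bit grayscale PNG using the map's display scaling
#' (`<name>.png`, masked pixels at the sentinel gray 0). The QC mask is
#' written as `qc_mask.png` (white = valid) and a `ranges.txt` sidecar
#' records, per map, the value range displayed and the mask sentinel.
#'
#' @param maps A [compute_maps()] result.
#' @param out_dir Output directory (created if needed).
#' @param ranges Optional named list of `c(lo, hi)` display ranges; maps
#'   not listed use the automatic percentile range.
#' @return Invisibly, the vector of files written.
#' @export
write_parameter_maps <- function(maps, out_dir, ranges = list()) {
  stopifnot(inherits(maps, "cbf_maps"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  params <- c("t_arrival", "t_rising", "mtt", "bfi")
  files <- character()
  sidecar <- c("# display ranges: parameter lo hi unit mask_gray")
  for (p in params) {
    txt <- file.path(out_dir, paste0(p, ".txt"))
    write_float_map(maps[[p]], txt)
    disp <- scale_for_display(maps[[p]], range = ranges[[p]])
    png_path <- file.path(out_dir, paste0(p, ".png"))
    png::writePNG(disp$image / 255, png_path)
    unit <- if (p == "bfi") "a.u./s" else "s"
    sidecar <- c(sidecar, sprintf("%s %.10g %.10g %s %d", p, disp$range[1],
                                  disp$range[2], unit, disp$mask_value))
    files <- c(files, txt, png_path)
  }
  qc_path <- file.path(out_dir, "qc_mask.png")
  png::writePNG(maps$qc * 1, qc_path)
  side_path <- file.path(out_dir, "ranges.txt")
  writeLines(sidecar, side_path)
  invisible(c(files, qc_path, side_path))
}

#' Exact float matrix text I/O
#'
#' Whitespace-delimited matrix of `%.17g`-formatted values; `NA` marks
#' masked pixels. The write/read round trip is value-exact for doubles.
#'
#' @param map Numeric matrix.
#' @param path File path.
#' @return `read_float_map()` returns the matrix; `write_float_map()`
#'   returns `path` invisibly.
#' @export
write_float_map <- function(map, path) {
  stopifnot(is.matrix(map))
  lines <- apply(map, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(sprintf("# rows %d cols %d", nrow(map), ncol(map)), lines), path)
  invisible(path)
}

#' @rdname write_float_map
#' @export
read_float_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  header <- strsplit(lines[1], " ")[[1]]
  nr <- as.integer(header[3]); nc <- as.integer(header[5])
  vals <- scan(text = lines[-1], what = numeric(), na.strings = c("NA", "nan"),
               quiet = TRUE)
  matrix(vals, nr, nc, byrow = TRUE)
}

#' Write the ROI summary report
#'
#' One CSV row per ROI per parameter: mean, standard error of the mean,
#' valid-pixel count and masked-pixel count, plus any test columns bound
#' by the caller. Numbers round-trip at full double precision.
#'
#' @param rows A data frame of ROI summaries (e.g. rbind-ed
#'   [roi_mean_params()] results).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_report <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  num <- vapply(rows, is.numeric, logical(1))
  out <- rows
  out[num] <- lapply(rows[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
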