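# Pipeline configuration: built-in acquisition/analysis defaults, YAML
# loading with strict key validation, and the config echo embedded in
# outputs.

.cbf_defaults <- list(
  frame_interval = 0.58,    # s per frame
  pixel_size = NULL,        # mm per pixel; acquisition-specific
  n_frames = 40,            # analysis window, frames
  smoothing_window = 7,     # Savitzky-Golay window, frames (odd)
  smoothing_order = 3,      # Savitzky-Golay polynomial order
  interp_dt = 0.0116,       # spline output step, s
  mtt_window = 20,          # MTT integration window after arrival, s
  qc_snr_threshold = 5      # amplitude / noise ratio to pass QC
)

#' Analysis configuration
#'
#' Holds every tunable of the pipeline with its default: 0.58 s frame
#' interval, 40-frame analysis window, third-order Savitzky-Golay
#' smoothing over 7 frames, 11.6 ms interpolation step, 20 s MTT window
#' and a QC signal-to-noise threshold of 5. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return An object of class `cbf_config`.
#' @examples
#' cbf_config(n_frames = 60)$n_frames
#' @export
cbf_config <- function(...) {
  over <- list(...)
  cfg <- .cbf_defaults
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("config overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  validate_config(structure(cfg, class = "cbf_config"))
}

validate_config <- function(cfg) {
  stopifnot(cfg$frame_interval > 0, cfg$n_frames >= 2,
            cfg$smoothing_window %% 2 == 1,
            cfg$smoothing_window > cfg$smoothing_order,
            cfg$smoothing_order >= 1, cfg$interp_dt > 0, cfg$mtt_window > 0,
            cfg$qc_snr_threshold >= 0)
  if (!is.null(cfg$pixel_size)) stopifnot(cfg$pixel_size > 0)
  cfg
}

#' @export
print.cbf_config <- function(x, ...) {
  cat("<cbf_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-17s %s\n", k,
                if (is.null(x[[k]])) "<unset>" else format(x[[k]])))
  }
  invisible(x)
}

#' Read a configuration file
#'
#' YAML with nested sections mirroring the pipeline stages:
#' `acquisition: {frame_interval, pixel_size}`,
#' `analysis: {n_frames}`, `smoothing: {window, order}`,
#' `interpolation: {dt}`, `mtt: {window_s}`, `qc: {snr_threshold}`.
#' Values not present fall back to the built-in defaults; unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @param base A [cbf_config] supplying the fallback values.
#' @return A validated [cbf_config].
#' @export
read_config <- function(path, base = cbf_config()) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  key_map <- list(
    acquisition = c(frame_interval = "frame_interval",
                    pixel_size = "pixel_size"),
    analysis = c(n_frames = "n_frames"),
    smoothing = c(window = "smoothing_window", order = "smoothing_order"),
    interpolation = c(dt = "interp_dt"),
    mtt = c(window_s = "mtt_window"),
    qc = c(snr_threshold = "qc_snr_threshold")
  )
  unknown_sections <- setdiff(names(raw), names(key_map))
  if (length(unknown_sections)) {
    stop("unknown config sections: ", paste(unknown_sections, collapse = ", "),
         call. = FALSE)
  }
  cfg <- unclass(base)
  for (sec in names(raw)) {
    keys <- key_map[[sec]]
    unknown <- setdiff(names(raw[[sec]]), names(keys))
    if (length(unknown)) {
      stop("unknown config keys in `", sec, "`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (k in names(raw[[sec]])) cfg[[keys[[k]]]] <- raw[[sec]][[k]]
  }
  validate_config(structure(cfg, class = "cbf_config"))
}

#' Write the effective configuration next to pipeline outputs
#'
#' @param config A [cbf_config].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cbf_config"))
  out <- list(
    acquisition = list(frame_interval = config$frame_interval,
                       pixel_size = config$pixel_size),
    analysis = list(n_frames = config$n_frames),
    smoothing = list(window = config$smoothing_window,
                     order = config$smoothing_order),
    interpolation = list(dt = config$interp_dt),
    mtt = list(window_s = config$mtt_window),
    qc = list(snr_threshold = config$qc_snr_threshold)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
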