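# Command-line orchestration: `cbfmap <compute|simulate|roi|trace>`.
# Each subcommand is a thin wrapper over the exported functions; logging
# goes to stderr with one machine-parseable summary line per stage.

#' Run the cbfmap pipeline
#'
#' Entry point used by the `cbfmap` command-line script
#' (`system.file("cli", "cbfmap", package = "cbfmap")`). Subcommands:
#'
#' * `simulate`: generate a phantom stack (`--preset`, `--seed`,
#'   `--noise-sigma`, `--out`, `--truth`).
#' * `compute`: compute parameter maps from a TIFF stack (`--input`,
#'   `--frame-interval`, `--pixel-size`, `--out`, optional `--config`,
#'   `--bregma`, `--midline`).
#' * `roi`: summarise ROIs on a map directory written by `compute`
#'   (`--maps`, `--bregma`, `--midline`, `--center-mm`, `--size-mm`,
#'   `--pixel-size`, `--mirror`, `--out`).
#' * `trace`: analyse a single two-column CSV trace (`--input`,
#'   `--frame-interval`) and print the kinetic record as JSON.
#'
#' Configuration precedence is CLI flag > config file > built-in
#' defaults; the effective configuration is echoed into the output
#' directory as `config.yaml`.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return The subcommand's main artifact, invisibly (maps, phantom, ROI
#'   report or kinetic record); errors raise conditions that the CLI
#'   script converts to exit status 1 plus usage text.
#' @export
run_pipeline <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: cbfmap <compute|simulate|roi|trace> [options]", call. = FALSE)
  }
  cmd <- args[1]
  rest <- args[-1]
  invisible(switch(cmd,
    compute = cli_compute(rest),
    simulate = cli_simulate(rest),
    roi = cli_roi(rest),
    trace = cli_trace(rest),
    stop("unknown subcommand `", cmd,
         "`; usage: cbfmap <compute|simulate|roi|trace> [options]",
         call. = FALSE)
  ))
}

stage_log <- function(stage, ...) {
  message(sprintf("[cbfmap] stage=%s %s", stage,
                  paste(sprintf("%s=%s", names(c(...)), c(...)),
                        collapse = " ")))
}

parse_pair <- function(x, what) {
  v <- suppressWarnings(as.numeric(strsplit(x, ",")[[1]]))
  if (length(v) != 2 || anyNA(v)) {
    stop("expected `R,C` numbers for ", what, call. = FALSE)
  }
  v
}

cli_parse <- function(spec, args) {
  parser <- optparse::OptionParser(option_list = spec)
  optparse::parse_args(parser, args = args)
}

cli_compute <- function(args) {
  opts <- cli_parse(list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--frame-interval", type = "double",
                          dest = "frame_interval"),
    optparse::make_option("--pixel-size", type = "double",
                          dest = "pixel_size"),
    optparse::make_option("--bregma", type = "character"),
    optparse::make_option("--midline", type = "integer"),
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--n-frames", type = "integer", dest = "n_frames"),
    optparse::make_option("--out", type = "character")
  ), args)
  if (is.null(opts$input) || is.null(opts$out)) {
    stop("compute requires --input and --out", call. = FALSE)
  }
  config <- if (!is.null(opts$config)) read_config(opts$config) else cbf_config()
  cfg <- unclass(config)
  for (k in c("frame_interval", "pixel_size", "n_frames")) {
    if (!is.null(opts[[k]])) cfg[[k]] <- opts[[k]]
  }
  config <- do.call(cbf_config, cfg[!vapply(cfg, is.null, logical(1))])
  t0 <- proc.time()["elapsed"]
  stack <- read_stack(opts$input, frame_interval = config$frame_interval,
                      pixel_size = config$pixel_size,
                      bregma_px = if (!is.null(opts$bregma))
                        parse_pair(opts$bregma, "--bregma"),
                      midline_col = opts$midline)
  stage_log("read", frames = dim(stack$frames)[1],
            rows = dim(stack$frames)[2], cols = dim(stack$frames)[3])
  maps <- compute_maps(stack, config)
  stage_log("maps", valid = sum(maps$qc), qc_failed = maps$n_qc_failed,
            elapsed_s = sprintf("%.1f", proc.time()["elapsed"] - t0))
  files <- tryCatch(
    write_parameter_maps(maps, opts$out),
    error = function(e) {
      unlink(opts$out, recursive = TRUE)
      stop(e)
    })
  write_config(config, file.path(opts$out, "config.yaml"))
  stage_log("write", out = opts$out, files = length(files) + 1L)
  invisible(maps)
}

cli_simulate <- function(args) {
  opts <- cli_parse(list(
    optparse::make_option("--preset", type = "character", default = "normal"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--noise-sigma", type = "double", default = 12,
                          dest = "noise_sigma"),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--truth", type = "character")
  ), args)
  if (is.null(opts$out)) stop("simulate requires --out", call. = FALSE)
  spec <- phantom_spec(preset = opts$preset, seed = opts$seed,
                       noise_sigma = opts$noise_sigma)
  ph <- generate_phantom(spec)
  write_stack(ph$stack, opts$out)
  stage_log("simulate", preset = opts$preset, seed = opts$seed,
            out = opts$out)
  if (!is.null(opts$truth)) {
    dir.create(opts$truth, recursive = TRUE, showWarnings = FALSE)
    for (p in names(ph$truth)) {
      write_float_map(ph$truth[[p]],
                      file.path(opts$truth, paste0(p, "_truth.txt")))
    }
    writeLines(as.vector(ph$labels),
               file.path(opts$truth, "region_labels.txt"))
    stage_log("truth", out = opts$truth)
  }
  invisible(ph)
}

cli_roi <- function(args) {
  opts <- cli_parse(list(
    optparse::make_option("--maps", type = "character"),
    optparse::make_option("--bregma", type = "character"),
    optparse::make_option("--midline", type = "integer"),
    optparse::make_option("--pixel-size", type = "double",
                          dest = "pixel_size"),
    optparse::make_option("--center-mm", type = "character",
                          dest = "center_mm", default = "2,2"),
    optparse::make_option("--size-mm", type = "character",
                          dest = "size_mm", default = "2,2"),
    optparse::make_option("--mirror", action = "store_true", default = FALSE),
    optparse::make_option("--out", type = "character")
  ), args)
  for (req in c("maps", "bregma", "pixel_size", "out")) {
    if (is.null(opts[[req]])) {
      stop("roi requires --maps, --bregma, --pixel-size and --out",
           call. = FALSE)
    }
  }
  maps <- read_map_dir(opts$maps)
  bregma <- parse_pair(opts$bregma, "--bregma")
  roi <- make_roi(parse_pair(opts$center_mm, "--center-mm"),
                  parse_pair(opts$size_mm, "--size-mm"),
                  pixel_size = opts$pixel_size, bregma_px = bregma,
                  shape = dim(maps$qc))
  report <- roi_mean_params(maps, roi, label = "ipsilateral")
  if (opts$mirror) {
    if (is.null(opts$midline)) {
      stop("--mirror requires --midline", call. = FALSE)
    }
    mroi <- mirror_roi(roi, opts$midline, shape = dim(maps$qc))
    report <- rbind(report,
                    roi_mean_params(maps, mroi, label = "contralateral"))
  }
  write_roi_report(report, opts$out)
  stage_log("roi", rows = nrow(report), out = opts$out)
  invisible(report)
}

# Rebuild a minimal cbf_maps object from a directory written by
# write_parameter_maps(); validity is taken from the non-NA pattern of the
# float maps.
read_map_dir <- function(dir) {
  params <- c("t_arrival", "t_rising", "mtt", "bfi")
  maps <- lapply(params, function(p) {
    path <- file.path(dir, paste0(p, ".txt"))
    if (!file.exists(path)) stop("missing map file: ", path, call. = FALSE)
    read_float_map(path)
  })
  names(maps) <- params
  maps$qc <- is.finite(maps$t_arrival)
  maps$config <- cbf_config()
  structure(maps, class = "cbf_maps")
}

cli_trace <- function(args) {
  opts <- cli_parse(list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--frame-interval", type = "double",
                          dest = "frame_interval")
  ), args)
  if (is.null(opts$input)) stop("trace requires --input", call. = FALSE)
  config <- if (!is.null(opts$config)) read_config(opts$config) else cbf_config()
  trace <- read_trace_csv(opts$input)
  kp <- analyze_trace(trace, config)
  stage_log("trace", valid = kp$valid)
  cat(format(kp), "\n")
  invisible(kp)
}
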