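# Synthetic bolus traces and phantom stacks with analytic ground truth.
# The first pass is a peak-normalized gamma-variate; recirculation is a sum
# of delayed, dispersion-widened gamma-variates; an exponential clearance
# term damps the late tail. Ground truth for every kinetic parameter is
# available in closed form or by fine quadrature, which makes the whole
# analysis pipeline testable without animal data.

#' Bolus model parameters
#'
#' Describes one region's dye kinetics: a gamma-variate first pass plus
#' optional recirculation peaks and exponential clearance.
#'
#' @param t0 Bolus onset time, seconds.
#' @param alpha Gamma-variate shape (dimensionless, > 0).
#' @param beta Gamma-variate timescale, seconds (> 0). The first-pass rise
#'   time is `alpha * beta` when `clearance_rate = 0`.
#' @param amplitude First-pass peak height, intensity units (the
#'   gamma-variate is peak-normalized).
#' @param recirc Recirculation peaks: a list of numeric triples
#'   `c(delay_s, relative_amplitude, dispersion)` (delays after `t0`,
#'   strictly increasing; dispersion multiplies `beta`).
#' @param baseline Pre-bolus intensity offset.
#' @param clearance_rate Late-time exponential decay rate, 1/s.
#' @return An object of class `bolus_params`.
#' @export
bolus_params <- function(t0 = 0, alpha = 3, beta = 0.9, amplitude = 1,
                         recirc = list(), baseline = 0, clearance_rate = 0) {
  stopifnot(alpha > 0, beta > 0, amplitude >= 0, baseline >= 0,
            clearance_rate >= 0)
  rc <- if (length(recirc)) do.call(rbind, recirc) else
    matrix(numeric(), 0, 3)
  colnames(rc) <- c("delay", "rel_amp", "dispersion")
  if (nrow(rc)) {
    stopifnot(all(rc[, "delay"] > 0), all(diff(rc[, "delay"]) > 0),
              all(rc[, "rel_amp"] >= 0), all(rc[, "dispersion"] > 0))
  }
  structure(list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude,
                 recirc = rc, baseline = baseline,
                 clearance_rate = clearance_rate),
            class = "bolus_params")
}

#' Peak-normalized gamma-variate
#'
#' The first-pass bolus shape: 0 for `t < t0`, and
#' `amplitude * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0) / beta)`
#' for `t >= t0`. The normalization puts the peak, of height `amplitude`,
#' at `t = t0 + alpha * beta`.
#'
#' @param t Time values, seconds (vectorized).
#' @param params A [bolus_params] (only the first-pass fields are used).
#' @return Intensities at `t`.
#' @export
gamma_variate <- function(t, params) {
  stopifnot(inherits(params, "bolus_params"))
  tau <- t - params$t0
  out <- numeric(length(t))
  pos <- tau > 0
  with(params, {
    out[pos] <- amplitude * (tau[pos] / (alpha * beta))^alpha *
      exp(alpha - tau[pos] / beta)
    out
  })
}

#' Noiseless bolus model curve
#'
#' First pass plus recirculation peaks, damped by exponential clearance
#' after onset, on top of the baseline.
#'
#' @inheritParams gamma_variate
#' @return Intensities at `t`.
#' @export
bolus_curve <- function(t, params) {
  stopifnot(inherits(params, "bolus_params"))
  v <- gamma_variate(t, params)
  rc <- params$recirc
  if (nrow(rc)) {
    for (k in seq_len(nrow(rc))) {
      pk <- bolus_params(
        t0 = params$t0 + rc[k, "delay"], alpha = params$alpha,
        beta = params$beta * rc[k, "dispersion"],
        amplitude = params$amplitude * rc[k, "rel_amp"]
      )
      v <- v + gamma_variate(t, pk)
    }
  }
  damp <- exp(-params$clearance_rate * pmax(t - params$t0, 0))
  params$baseline + damp * v
}

#' Simulate one noisy trace from a bolus model
#'
#' Evaluates the model curve on `t_grid`, adds zero-mean Gaussian camera
#' noise, and (when `bit_depth` is given) quantizes to integer digital
#' numbers clipped to `[0, 2^bit_depth - 1]`. Deterministic per seed.
#'
#' @param params A [bolus_params].
#' @param t_grid Uniform time grid, seconds.
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param bit_depth Optional integer; when given, output is rounded and
#'   clipped to the sensor range.
#' @return A [cbf_trace].
#' @export
simulate_trace <- function(params, t_grid, noise_sigma = 0, seed = NULL,
                           bit_depth = NULL) {
  v <- bolus_curve(t_grid, params)
  if (noise_sigma > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, noise_sigma))
  }
  if (!is.null(bit_depth)) {
    v <- pmin(pmax(round(v), 0), 2^bit_depth - 1)
  }
  cbf_trace(t_grid, v)
}

# Run `expr` under a temporary RNG state seeded with `seed` (if non-NULL),
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Tissue-class bolus presets
#'
#' Plausible mouse-head kinetics for the phantom's tissue classes, chosen
#' to reproduce the qualitative structure of in-vivo dye dynamics: the
#' cerebrum peaks earliest; the large draining vein peaks slightly later
#' with a higher amplitude; extracranial skeletal muscle has a weak first
#' pass whose later recirculation peaks exceed it; the ischemic cerebrum
#' preset is the cerebrum delayed by 2.9 s (five frames) with a slower,
#' weaker first pass.
#'
#' @param name One of `"cerebrum"`, `"vein"`, `"muscle"`, `"ischemic"`,
#'   `"background"`.
#' @return A [bolus_params].
#' @export
bolus_preset <- function(name = c("cerebrum", "vein", "muscle", "ischemic",
                                  "background")) {
  switch(match.arg(name),
    cerebrum = bolus_params(
      t0 = 4.06, alpha = 3, beta = 0.9, amplitude = 2600,
      recirc = list(c(10, 0.30, 2.2), c(17, 0.15, 3.0)),
      baseline = 120, clearance_rate = 0.010
    ),
    vein = bolus_params(
      t0 = 4.64, alpha = 3, beta = 1.1, amplitude = 3300,
      recirc = list(c(10, 0.35, 2.2), c(17, 0.18, 3.0)),
      baseline = 130, clearance_rate = 0.010
    ),
    muscle = bolus_params(
      t0 = 5.22, alpha = 3, beta = 1.6, amplitude = 900,
      recirc = list(c(8, 1.5, 2.0), c(16, 0.9, 2.8)),
      baseline = 110, clearance_rate = 0.015
    ),
    ischemic = bolus_params(
      t0 = 6.96, alpha = 3, beta = 1.7, amplitude = 1500,
      recirc = list(c(8, 0.80, 2.2), c(14, 0.50, 3.0)),
      baseline = 120, clearance_rate = 0.010
    ),
    background = bolus_params(t0 = 4.06, alpha = 3, beta = 0.9, amplitude = 0,
                              baseline = 110)
  )
}

#' Phantom scene specification
#'
#' A labelled 2D scene in which every region follows one bolus model. The
#' default geometry is a 64 x 64 scene with two cerebral hemispheres
#' (ellipses either side of the midline), a sagittal-vein strip on the
#' midline, a posterior muscle band and signal-free background, imaged for
#' 40 frames at 0.58 s per frame with 12-bit quantization. The
#' `"ischemic"` preset replaces the left-hemisphere kinetics with the
#' delayed, attenuated ischemic bolus.
#'
#' @param shape `(rows, cols)` of the scene.
#' @param preset `"normal"` or `"ischemic"` built-in scene, ignored when
#'   `regions` is supplied.
#' @param regions Optional named list of regions, each a list with a
#'   logical `mask` matrix and a [bolus_params] `params`. Masks must be
#'   disjoint; unlabelled pixels are background (no signal).
#' @param noise_sigma Gaussian camera-noise standard deviation in digital
#'   numbers (default 12).
#' @param bit_depth Sensor bit depth (default 12).
#' @param seed Integer seed for the noise (default 1).
#' @param frame_interval Seconds per frame (default 0.58).
#' @param n_frames Number of frames (default 40).
#' @param pixel_size mm per pixel (default 0.2).
#' @param bregma_px `(row, col)` of the bregma landmark.
#' @param midline_col Column index of the sagittal midline.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64), preset = c("normal", "ischemic"),
                         regions = NULL, noise_sigma = 12, bit_depth = 12,
                         seed = 1, frame_interval = 0.58, n_frames = 40,
                         pixel_size = 0.2, bregma_px = c(26, 32),
                         midline_col = 32) {
  preset <- match.arg(preset)
  if (is.null(regions)) {
    regions <- default_phantom_regions(shape, ischemic = preset == "ischemic")
  }
  cover <- matrix(0L, shape[1], shape[2])
  for (rg in regions) {
    stopifnot(is.logical(rg$mask), all(dim(rg$mask) == shape),
              inherits(rg$params, "bolus_params"))
    cover <- cover + rg$mask
  }
  if (any(cover > 1L)) stop("region masks overlap", call. = FALSE)
  structure(list(shape = shape, regions = regions, noise_sigma = noise_sigma,
                 bit_depth = bit_depth, seed = seed,
                 frame_interval = frame_interval, n_frames = n_frames,
                 pixel_size = pixel_size, bregma_px = bregma_px,
                 midline_col = midline_col, preset = preset),
            class = "phantom_spec")
}

# Scene geometry in fractions of the image so any shape works; at the
# default 64 x 64 this gives hemisphere ellipses centred at (30, 20) and
# (30, 44) with semi-axes (14, 9), a 3-column midline vein strip and a
# posterior muscle band.
default_phantom_regions <- function(shape, ischemic = FALSE) {
  nr <- shape[1]; nc <- shape[2]
  ellipse <- function(c_r, c_c, a_r, a_c) {
    r <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    ((r - c_r) / a_r)^2 + ((cc - c_c) / a_c)^2 <= 1
  }
  rect <- function(rows, cols) {
    m <- matrix(FALSE, nr, nc)
    m[rows, cols] <- TRUE
    m
  }
  frac <- function(f, n) max(1L, min(n, as.integer(round(f * n))))
  vein_rows <- frac(0.25, nr):frac(0.69, nr)
  vein_cols <- frac(0.48, nc):frac(0.52, nc)
  left <- ellipse(0.47 * nr, 0.31 * nc, 0.22 * nr, 0.14 * nc)
  right <- ellipse(0.47 * nr, 0.69 * nc, 0.22 * nr, 0.14 * nc)
  vein <- rect(vein_rows, vein_cols) & !left & !right
  muscle <- rect(frac(0.84, nr):frac(0.97, nr), frac(0.08, nc):frac(0.94, nc))
  left <- left & !rect(vein_rows, vein_cols)
  right <- right & !rect(vein_rows, vein_cols)
  list(
    cerebrum_left = list(
      mask = left,
      params = bolus_preset(if (ischemic) "ischemic" else "cerebrum")
    ),
    cerebrum_right = list(mask = right, params = bolus_preset("cerebrum")),
    sagittal_vein = list(mask = vein, params = bolus_preset("vein")),
    muscle = list(mask = muscle, params = bolus_preset("muscle"))
  )
}

#' Generate a phantom stack with analytic ground truth
#'
#' Simulates every pixel's trace from its region's bolus model (shared
#' noiseless curve per region, independent Gaussian noise per pixel,
#' quantized to the sensor bit depth) and returns the stack together with
#' ground-truth parameter maps computed analytically from the model:
#' arrival = `t0`; rising time and blood flow index from the closed-form
#' first-pass peak (`tau_peak = alpha*beta / (1 + clearance_rate*beta)`,
#' which reduces to `alpha*beta` without clearance); mean transit time by
#' fine trapezoidal quadrature of the noiseless baseline-zeroed model over
#' the effective post-arrival window. Background pixels hold `NA` truth.
#'
#' @param spec A [phantom_spec].
#' @return A list with `stack` (an [acq_stack]), `truth` (list of
#'   `t_arrival`, `t_rising`, `mtt`, `bfi` matrices), `labels` (character
#'   matrix of region names, `"background"` elsewhere) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]; nt <- spec$n_frames
  t_grid <- (seq_len(nt) - 1) * spec$frame_interval
  frames <- array(0, dim = c(nt, nr, nc))
  bg <- bolus_preset("background")
  base_curve <- bolus_curve(t_grid, bg)
  for (k in seq_len(nt)) frames[k, , ] <- base_curve[k]

  labels <- matrix("background", nr, nc)
  truth <- list(t_arrival = matrix(NA_real_, nr, nc),
                t_rising = matrix(NA_real_, nr, nc),
                mtt = matrix(NA_real_, nr, nc),
                bfi = matrix(NA_real_, nr, nc))
  t_end <- t_grid[nt]
  for (nm in names(spec$regions)) {
    rg <- spec$regions[[nm]]
    curve <- bolus_curve(t_grid, rg$params)
    idx <- which(rg$mask)
    for (k in seq_len(nt)) {
      plane <- frames[k, , ]
      plane[idx] <- curve[k]
      frames[k, , ] <- plane
    }
    labels[idx] <- nm
    tr <- bolus_truth(rg$params, t_end = t_end)
    truth$t_arrival[idx] <- tr$t_arrival
    truth$t_rising[idx] <- tr$t_rising
    truth$mtt[idx] <- tr$mtt
    truth$bfi[idx] <- tr$bfi
  }

  if (spec$noise_sigma > 0) {
    frames <- frames + with_seed(
      spec$seed, array(stats::rnorm(nt * nr * nc, 0, spec$noise_sigma),
                       dim = c(nt, nr, nc)))
  }
  frames <- pmin(pmax(round(frames), 0), 2^spec$bit_depth - 1)

  stack <- acq_stack(frames, frame_interval = spec$frame_interval,
                     pixel_size = spec$pixel_size, bregma_px = spec$bregma_px,
                     midline_col = spec$midline_col,
                     bit_depth = spec$bit_depth)
  list(stack = stack, truth = truth, labels = labels, spec = spec)
}

#' Analytic ground truth for one bolus model
#'
#' @param params A [bolus_params].
#' @param window MTT window in seconds (default 20).
#' @param t_end End of the acquisition in seconds (used to clip the MTT
#'   window as the analyzer must); default `Inf` (no clipping).
#' @return List with `t_arrival`, `t_rising`, `bfi`, `mtt`, `i_peak`.
#' @export
bolus_truth <- function(params, window = 20, t_end = Inf) {
  stopifnot(inherits(params, "bolus_params"))
  a <- params$alpha; b <- params$beta; cl <- params$clearance_rate
  tau_pk <- a * b / (1 + cl * b)
  i_pk <- params$amplitude * (tau_pk / (a * b))^a *
    exp(a - tau_pk / b) * exp(-cl * tau_pk)
  w_eff <- min(window, t_end - params$t0)
  tau <- seq(0, w_eff, length.out = 20001)
  y <- bolus_curve(params$t0 + tau, params) - params$baseline
  mtt <- pracma::trapz(tau, tau * y) / pracma::trapz(tau, y)
  list(t_arrival = params$t0, t_rising = tau_pk, bfi = i_pk / tau_pk,
       mtt = mtt, i_peak = i_pk)
}
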