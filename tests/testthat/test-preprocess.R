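test_that("Savitzky-Golay smoothing is the local least-squares fit", {
  # constants and cubics lie in the fit space, so they pass through intact
  tt <- native_grid(9)
  const <- cbf_trace(tt, rep(5, 9))
  expect_equal(smooth_trace(const, 7, 3)$intensity, rep(5, 9))

  cubic <- cbf_trace(tt, tt^3)
  expect_equal(smooth_trace(cubic, 7, 3)$intensity, tt^3, tolerance = 1e-12)

  # white noise: every interior point must equal the explicit sliding
  # least-squares fit
  set.seed(401)
  y <- rnorm(200)
  tr <- cbf_trace(native_grid(200), y)
  ours <- smooth_trace(tr, 7, 3)$intensity
  oracle <- sg_lm_oracle(y, 7, 3)
  interior <- !is.na(oracle)
  expect_lt(max(abs(ours[interior] - oracle[interior])), 1e-10)

  # cross-check against an established filter implementation (interior)
  ref <- signal::sgolayfilt(y, p = 3, n = 7)
  expect_lt(max(abs(ours[interior] - ref[interior])), 1e-9)
})

test_that("smoothing rejects invalid windows", {
  tr <- cbf_trace(native_grid(10), rnorm(10))
  expect_error(smooth_trace(tr, 6, 3), "odd")
  expect_error(smooth_trace(tr, 3, 3), "exceed")
  expect_error(smooth_trace(tr, 11, 3), "length")
})

test_that("smoothing and interpolation are linear and time-equivariant", {
  set.seed(402)
  for (k in 1:4) {
    y <- cumsum(rnorm(40))
    tt <- native_grid(40)
    tr <- cbf_trace(tt, y)
    delta <- runif(1, -5, 5)
    scale <- runif(1, 0.1, 10)

    sm <- smooth_trace(tr)
    sm_shift <- smooth_trace(cbf_trace(tt + delta, y))
    expect_equal(sm_shift$intensity, sm$intensity)
    expect_equal(sm_shift$t, sm$t + delta)
    expect_equal(smooth_trace(cbf_trace(tt, scale * y))$intensity,
                 scale * sm$intensity)

    ip <- interpolate_trace(tr)
    ip_shift <- interpolate_trace(cbf_trace(tt + delta, y))
    expect_equal(ip_shift$intensity, ip$intensity)
    expect_equal(interpolate_trace(cbf_trace(tt, scale * y))$intensity,
                 scale * ip$intensity)
  }
})

test_that("spline interpolation hits the 11.6 ms grid and the samples", {
  tt <- native_grid(40)
  set.seed(403)
  tr <- cbf_trace(tt, rnorm(40, 100, 5))
  out <- interpolate_trace(tr)                    # default 0.0116 s
  expect_equal(out$dt, 0.0116)
  expect_equal(length(out$t), 39 * 50 + 1)        # 50 substeps per frame
  # interpolant passes through every original sample
  at_knots <- out$intensity[match(round(tt, 9), round(out$t, 9))]
  expect_equal(at_knots, tr$intensity, tolerance = 1e-9)

  # straight lines are reproduced everywhere
  lin <- interpolate_trace(cbf_trace(tt, 2 + 3 * tt))
  expect_equal(lin$intensity, 2 + 3 * lin$t, tolerance = 1e-9)

  # identity on the samples when dt_out equals the native step
  same <- interpolate_trace(tr, dt_out = tr$dt)
  expect_equal(same$t, tr$t)
  expect_equal(same$intensity, tr$intensity, tolerance = 1e-12)

  expect_error(interpolate_trace(tr, 0), "positive")
  expect_error(interpolate_trace(tr, 1), "native")
})

test_that("analysis window selection keeps the initial frames", {
  frames <- array(rep(1:300, 4), dim = c(300, 2, 2))
  stack <- acq_stack(frames, frame_interval = 0.58)
  win <- select_analysis_window(stack)
  expect_equal(dim(win$frames)[1], 40)
  expect_equal(win$frames[, 1, 1], 1:40)

  short <- acq_stack(frames[1:30, , , drop = FALSE], frame_interval = 0.58)
  expect_warning(kept <- select_analysis_window(short, 40), "only 30")
  expect_equal(dim(kept$frames)[1], 30)

  expect_error(select_analysis_window(stack, 1), ">= 2")
})

test_that("baseline is the pre-arrival mean with a minimum-rule fallback", {
  tt <- native_grid(20, dt = 0.5)
  flat_then_bolus <- c(rep(100, 5), 100 + 50 * (1:15))
  tr <- cbf_trace(tt, flat_then_bolus)
  expect_equal(estimate_baseline(tr, t_arrival = 2), 100)

  # one pre-arrival sample: fall back to the minimum with a warning
  expect_warning(b <- estimate_baseline(tr, t_arrival = tt[2]), "fallback|minimum")
  expect_equal(b, min(flat_then_bolus))

  # no arrival supplied: minimum rule, silent
  expect_equal(estimate_baseline(tr), 100)

  # noisy pre-arrival plateau: exactly the sample mean of those points
  set.seed(404)
  pre <- rnorm(500, 50, 1)
  tr2 <- cbf_trace(native_grid(600, dt = 0.01),
                   c(pre, 50 + 40 * gamma_raw(1:100 / 100, alpha = 2)))
  expect_equal(estimate_baseline(tr2, t_arrival = 500 * 0.01), mean(pre))
})

test_that("QC passes real boluses, rejects noise, and matches its formula", {
  tg <- native_grid()
  bolus <- bolus_curve(tg, bolus_preset("cerebrum"))

  # noiseless bolus of large amplitude passes at any finite threshold
  st <- stack_from_traces(cbind(bolus), 2, 2)
  expect_true(all(qc_mask(st, snr_threshold = 1e6)))

  # a pure-noise pixel (sigma 1, amplitude 0) fails at threshold 5
  set.seed(405)
  noise <- matrix(rnorm(40 * 4, 100, 1), 40)
  expect_false(any(qc_mask(stack_from_traces(noise, 2, 2))))

  # random per-pixel amplitudes, sigma 2: the mask must agree 100% with a
  # direct per-pixel evaluation of the amplitude/noise rule
  set.seed(406)
  nr <- 6; nc <- 8
  amps <- matrix(runif(nr * nc, 0, 100), nr, nc)
  frames <- array(0, dim = c(40, nr, nc))
  shape <- gamma_raw(tg, t0 = 4, alpha = 3, beta = 1)
  shape <- shape / max(shape)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    frames[, r, cc] <- 100 + amps[r, cc] * shape + rnorm(40, 0, 2)
  }
  stack <- acq_stack(frames, frame_interval = 0.58)
  got <- qc_mask(stack, snr_threshold = 5)
  want <- matrix(NA, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    y <- frames[, r, cc]
    s <- smooth_trace(cbf_trace(tg, y), 7, 3)$intensity
    pk <- which.max(s)
    pre <- if (pk - 1 - 3 >= 8) seq_len(pk - 1 - 3) else seq_len(40)
    want[r, cc] <- (max(s) - mean(s[pre])) >= 5 * mad(y[pre] - s[pre])
  }
  expect_identical(as.vector(got), as.vector(want))
})
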