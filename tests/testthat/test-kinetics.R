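test_that("the half-intensity time is the first median crossing", {
  tr <- cbf_trace(0:9, c(0, 1, 2, 10, 8, 6, 5, 4, 3, 2))
  th <- find_t_half(tr)                 # median 3.5; first I >= 3.5 is I = 10
  expect_equal(as.numeric(th), 3)

  # strictly increasing ramp of odd length: t_half at the middle sample
  ramp <- cbf_trace(0:10, seq(2, 22, by = 2))
  expect_equal(as.numeric(find_t_half(ramp)), 5)

  # gamma-variate trace: agree exactly with a sort-and-scan oracle
  tg <- seq(0, 23.2, by = 0.0116)
  y <- gamma_raw(tg, t0 = 3, alpha = 2, beta = 1)
  tr2 <- cbf_trace(tg, y)
  med <- sort(y)[ceiling(length(y) / 2)]          # odd length: middle order stat
  oracle_idx <- which(y >= med)[1]
  expect_equal(as.numeric(find_t_half(tr2)), tg[oracle_idx])

  expect_error(find_t_half(cbf_trace(0:9, rep(7, 10))), class = "cbf_kinetics_error")
})

test_that("backward tracing finds the arrival at the foot of the rise", {
  # hand-traced example: from I = 6 back through 2 and 0, then 5 >= 0 stops
  tr <- cbf_trace(0:5, c(5, 5, 0, 2, 6, 10))
  arr <- trace_to_arrival(tr, 4)
  expect_equal(arr$t_arrival, 2)
  expect_equal(arr$i_arrival, 0)

  # strictly monotone rise runs back to the first sample
  mono <- cbf_trace(0:9, 2^(0:9))
  th <- find_t_half(mono)
  expect_equal(trace_to_arrival(mono, th)$t_arrival, 0)

  # t_half at the first sample: arrival equals it, with a warning
  expect_warning(a0 <- trace_to_arrival(tr, 0), "first sample")
  expect_equal(a0$t_arrival, 0)

  # noiseless gamma-variate on a fine grid: onset recovered within one step
  tg <- seq(0, 23.2, by = 0.0116)
  tr2 <- cbf_trace(tg, gamma_raw(tg, t0 = 3, alpha = 2, beta = 1))
  th2 <- find_t_half(tr2)
  expect_lt(abs(trace_to_arrival(tr2, th2)$t_arrival - 3), 0.0116 + 1e-12)
})

test_that("forward tracing stops at the first peak, not the global maximum", {
  tr <- cbf_trace(0:6, c(0, 2, 6, 10, 9, 11, 3))
  th <- find_t_half(tr)                  # median 6 -> first crossing at t = 2
  expect_equal(as.numeric(th), 2)
  pk <- trace_to_peak(tr, th)
  expect_equal(pk$t_peak, 3)
  expect_equal(pk$i_peak, 10)            # not the later 11
  expect_equal(tr$t[which.max(tr$intensity)], 5)

  # plateau terminates the climb at its first sample
  plat <- cbf_trace(0:6, c(0, 1, 2, 3, 4, 4, 4))
  expect_equal(trace_to_peak(plat, 1)$t_peak, 4)

  # two-peak muscle-like trace (weak first pass, dominant recirculation):
  # the first local maximum wins, the global argmax is a later peak
  tg <- seq(0, 23.2, by = 0.0116)
  y <- bolus_curve(tg, bolus_preset("muscle"))
  tr2 <- cbf_trace(tg, y)
  pk2 <- trace_to_peak(tr2, find_t_half(tr2))
  first_seg_max <- tg[which.max(y * (tg < 12))]   # argmax oracle, first pass
  expect_equal(pk2$t_peak, first_seg_max, tolerance = 1e-9)
  expect_gt(tg[which.max(y)], pk2$t_peak)
  expect_gt(max(y), pk2$i_peak)

  expect_error(trace_to_peak(tr, 6), class = "cbf_kinetics_error")
})

test_that("rising time and blood flow index follow their definitions", {
  expect_equal(rising_time(2.0, 4.7), 2.7)
  expect_equal(rising_time(3, 3), 0)
  expect_error(rising_time(4, 3), class = "cbf_kinetics_error")

  expect_equal(blood_flow_index(0, 10, 2), 5)
  expect_equal(blood_flow_index(7, 7, 2), 0)
  expect_error(blood_flow_index(0, 10, 0), class = "cbf_kinetics_error")

  # analytic gamma-variate example: peak 4 e^-2 at rise 2 s
  tg <- seq(0, 23.2, by = 0.0116)
  tr <- cbf_trace(tg, gamma_raw(tg, t0 = 3, alpha = 2, beta = 1))
  th <- find_t_half(tr)
  arr <- trace_to_arrival(tr, th)
  pk <- trace_to_peak(tr, th)
  rise <- rising_time(arr$t_arrival, pk$t_peak)
  expect_equal(rise, 2, tolerance = 0.05)
  expect_equal(blood_flow_index(arr$i_arrival, pk$i_peak, rise),
               4 * exp(-2) / 2, tolerance = 0.01)
})

test_that("MTT is the centroid of the post-arrival window", {
  # point mass: single nonzero sample at tau = 5
  tau <- seq(0, 20, by = 0.1)
  y <- numeric(length(tau)); y[tau == 5] <- 1
  expect_equal(mean_transit_time(cbf_trace(tau, y), 0), 5)

  # rectangle on [0, 8]: centroid at 4 within a grid step
  yr <- as.numeric(tau <= 8)
  expect_equal(mean_transit_time(cbf_trace(tau, yr), 0), 4, tolerance = 0.1)

  # smooth bolus vs fine-grid quadrature oracle, within 0.5%
  tg <- seq(0, 23.2, by = 0.0116)
  tr <- cbf_trace(tg, gamma_raw(tg, alpha = 2, beta = 1))
  got <- mean_transit_time(tr, 0)
  want <- mtt_quad_oracle(function(u) gamma_raw(u, alpha = 2, beta = 1))
  expect_lt(abs(got - want) / want, 0.005)
  expect_equal(want, 3.0, tolerance = 0.01)      # near the infinite-window value

  # window clipping warns; all-zero signal has no mass
  expect_warning(mean_transit_time(tr, 10, window = 20), "clipped")
  expect_error(mean_transit_time(cbf_trace(tau, numeric(length(tau))), 0),
               class = "cbf_kinetics_error")
})

test_that("analyze_trace composes the stages and flags failures", {
  cfg <- cbf_config()
  tg <- native_grid()

  flat <- analyze_trace(cbf_trace(tg, rep(100, 40)), cfg)
  expect_false(flat$valid)
  expect_equal(flat$reason, "flat")

  kp <- analyze_trace(simulate_trace(bolus_preset("cerebrum"), tg), cfg)
  expect_true(kp$valid)
  # ordering invariant on the time parameters
  expect_true(kp$t_arrival <= as.numeric(kp$t_half) + 1e-12)
  expect_true(kp$t_half <= kp$t_peak + 1e-12)
  expect_true(kp$t_peak <= kp$t_max + 1e-12)
  expect_gte(kp$i_max, kp$i_peak)
  expect_equal(kp$t_rising, kp$t_peak - kp$t_arrival)
  expect_gte(kp$bfi, 0)
  expect_true(kp$mtt >= 0 && kp$mtt <= cfg$mtt_window)
})

test_that("kinetic parameters are time-shift and intensity-scale equivariant", {
  cfg <- cbf_config()
  tg <- native_grid()
  set.seed(407)
  for (k in 1:4) {
    p <- bolus_params(t0 = runif(1, 3, 5), alpha = runif(1, 2, 4),
                      beta = runif(1, 0.7, 1.3),
                      amplitude = runif(1, 1000, 3000), baseline = 100)
    tr <- simulate_trace(p, tg, noise_sigma = 10, seed = 500 + k)
    ref <- analyze_trace(tr, cfg)
    expect_true(ref$valid)

    delta <- 1.16
    shifted <- analyze_trace(cbf_trace(tr$t + delta, tr$intensity), cfg)
    expect_equal(shifted$t_arrival, ref$t_arrival + delta, tolerance = 1e-9)
    expect_equal(shifted$t_peak, ref$t_peak + delta, tolerance = 1e-9)
    expect_equal(shifted$t_rising, ref$t_rising, tolerance = 1e-9)
    expect_equal(shifted$mtt, ref$mtt, tolerance = 1e-9)
    expect_equal(shifted$bfi, ref$bfi, tolerance = 1e-9)

    sc <- 2.5
    scaled <- analyze_trace(cbf_trace(tr$t, sc * tr$intensity), cfg)
    expect_equal(scaled$t_arrival, ref$t_arrival, tolerance = 0.0116)
    expect_equal(scaled$t_rising, ref$t_rising, tolerance = 0.0232)
    expect_equal(scaled$mtt, ref$mtt, tolerance = 1e-6)
    expect_equal(scaled$bfi, sc * ref$bfi, tolerance = 1e-6)
  }
})

test_that("a bolus delayed by whole frames shifts arrival and nothing else", {
  cfg <- cbf_config()
  tg <- native_grid()
  p <- bolus_preset("cerebrum")
  ref <- analyze_trace(simulate_trace(p, tg), cfg)
  p2 <- p; p2$t0 <- p$t0 + 1.16                  # two frames, on-grid
  del <- analyze_trace(simulate_trace(p2, tg), cfg)
  expect_equal(del$t_arrival - ref$t_arrival, 1.16, tolerance = 0.0116)
  expect_equal(del$t_rising, ref$t_rising, tolerance = 0.0116)
  expect_equal(del$bfi, ref$bfi, tolerance = 0.01 * ref$bfi)
})
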