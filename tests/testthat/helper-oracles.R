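# Shared fixtures and independent oracles, all built in code.

# Native camera grid: 40 frames at 0.58 s.
native_grid <- function(n = 40, dt = 0.58) (seq_len(n) - 1) * dt

# Brute-force sliding least-squares smoother: fits a degree-`order`
# polynomial by lm() over each full symmetric window and evaluates it at
# the centre. Covers interior points only (NA elsewhere). Independent of
# the package's weight-based implementation.
sg_lm_oracle <- function(y, window, order) {
  n <- length(y)
  h <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in (h + 1):(n - h)) {
    d <- data.frame(x = (-h):h, y = y[(i - h):(i + h)])
    fit <- stats::lm(y ~ poly(x, order, raw = TRUE), data = d)
    out[i] <- unname(stats::predict(fit, newdata = data.frame(x = 0)))
  }
  out
}

# Fine-grid trapezoidal centroid of an analytic curve f(tau) over
# [0, window]; the quadrature oracle for MTT.
mtt_quad_oracle <- function(f, window = 20, n = 200001) {
  tau <- seq(0, window, length.out = n)
  y <- f(tau)
  pracma::trapz(tau, tau * y) / pracma::trapz(tau, y)
}

# Classic (unnormalized) gamma-variate tau^alpha * exp(-tau/beta), zero
# before onset; used by the analytic worked examples.
gamma_raw <- function(t, t0 = 0, alpha = 2, beta = 1) {
  tau <- t - t0
  ifelse(tau <= 0, 0, tau^alpha * exp(-tau / beta))
}

# Build an acq_stack by tiling traces: `values` is a frames x pixels
# matrix assigned column-by-column into an nr x nc scene.
stack_from_traces <- function(values, nr, nc, frame_interval = 0.58, ...) {
  nt <- nrow(values)
  frames <- array(0, dim = c(nt, nr, nc))
  for (p in seq_len(nr * nc)) {
    row <- (p - 1) %% nr + 1
    col <- (p - 1) %/% nr + 1
    frames[, row, col] <- values[, ((p - 1) %% ncol(values)) + 1]
  }
  acq_stack(frames, frame_interval = frame_interval, ...)
}
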