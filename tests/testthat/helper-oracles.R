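# Shared helpers: independent constructions used as oracles.

# Sample a single half-wave function as a fragment starting at its onset,
# on a grid fine relative to the shape scale.
single_hwf_fragment <- function(sigma, beta, dt = max(sigma / 8, 1e-5),
                                span = 10 * (sigma + beta)) {
  t <- seq(0, span, by = dt)
  half_wave(hwf_eval(t, sigma, beta), dt = dt, tau = 0)
}

# Independent piecewise-linear interpolant of a half-wave: base-R linear
# interpolation of the samples on [0, T], plus the terminal ramp that takes
# a non-zero last sample linearly to zero over one extra step.
plin_interpolant <- function(hw) {
  n <- length(hw$samples)
  tt <- (seq_len(n) - 1) * hw$dt
  Tend <- tt[n]
  core <- approxfun(tt, hw$samples, yleft = 0, yright = 0)
  wN <- hw$samples[n]; dt <- hw$dt
  function(t) {
    out <- core(t)
    ramp <- t > Tend & t <= Tend + dt
    out[ramp] <- wN * (1 - (t[ramp] - Tend) / dt)
    out
  }
}

# Brute-force finite Fourier transform of the interpolant by adaptive
# quadrature, integrating piecewise between the sample knots so the kinks
# never degrade accuracy.
quad_transform <- function(hw, omegas) {
  h <- plin_interpolant(hw)
  n <- length(hw$samples)
  knots <- c((seq_len(n) - 1) * hw$dt, n * hw$dt)
  piece_int <- function(f) {
    sum(vapply(seq_len(length(knots) - 1), function(k)
      integrate(f, knots[k], knots[k + 1], rel.tol = 1e-11,
                abs.tol = 1e-14)$value, numeric(1)))
  }
  Wc <- vapply(omegas, function(om) piece_int(function(t) h(t) * cos(om * t)),
               numeric(1))
  Ws <- vapply(omegas, function(om) piece_int(function(t) h(t) * sin(om * t)),
               numeric(1))
  list(Wc = Wc, Ws = Ws, amplitude = sqrt(Wc^2 + Ws^2))
}

# Independent re-scan of the segmentation predicates at a single index.
segmentation_predicates <- function(v, m) {
  zc <- (v[m - 1] <= 0 && v[m + 1] > 0) || (v[m - 1] >= 0 && v[m + 1] < 0)
  am <- abs(v[m - 1]) >= abs(v[m]) && abs(v[m]) <= abs(v[m + 1])
  c(zero_crossing = zc, abs_minimum = am)
}
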