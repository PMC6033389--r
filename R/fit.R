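#' Normalize an amplitude spectrum
#'
#' Divides the amplitude spectrum by its value at a small reference
#' frequency \eqn{\omega_0} (chosen so that
#' \eqn{W(\omega_0) \approx W(0)}), giving the dimensionless
#' \eqn{W^*(\omega) = W(\omega)/W(\omega_0)} with \eqn{W^*(\omega_0) = 1}.
#' The normalizing value becomes the scaling coefficient
#' \eqn{\kappa = W(\omega_0)}, signed by the half-wave polarity.
#'
#' @param spectrum an `sbf_spectrum` on a grid whose first point is at or
#'   above `omega0`.
#' @param omega0 reference angular frequency (rad/s); defaults to the
#'   first grid point.
#' @param polarity +1 or -1; sign attached to `kappa`.
#' @return list with `Wstar` (dimensionless amplitude series) and
#'   `kappa` (uV s).
#' @export
normalize_amplitude <- function(spectrum, omega0 = spectrum$omegas[1],
                                polarity = 1) {
  stopifnot(inherits(spectrum, "sbf_spectrum"))
  w0 <- if (omega0 <= spectrum$omegas[1]) {
    spectrum$amplitude[1]
  } else {
    approx(spectrum$omegas, spectrum$amplitude, xout = omega0)$y
  }
  if (!is.finite(w0) || w0 <= 0) stop("W(omega0) vanishes; cannot normalize")
  list(Wstar = spectrum$amplitude / w0, kappa = sign(polarity) * w0)
}

#' Cutoff frequency of a normalized amplitude spectrum
#'
#' The cutoff \eqn{F_C} is the frequency at which the normalized
#' spectrum is attenuated by 3 dB, \eqn{W^*(\omega_C) = 1/\sqrt 2}.  The
#' crossing is located by log-linear interpolation between the grid
#' points that bracket it.
#'
#' @param omegas angular frequency grid (rad/s), increasing.
#' @param Wstar normalized amplitudes on the grid; must start at or above
#'   \eqn{1/\sqrt 2} and fall below it within the grid.
#' @return cutoff frequency \eqn{F_C} in Hz.
#' @export
estimate_cutoff <- function(omegas, Wstar) {
  thr <- 1 / sqrt(2)
  if (Wstar[1] < thr) stop("spectrum starts below the 3 dB level")
  below <- which(Wstar < thr)
  if (length(below) == 0L) stop("no 3 dB crossing within the frequency grid")
  j <- below[1L]
  # log-linear interpolation in omega between points j-1 and j
  lo <- j - 1L
  frac <- (thr - Wstar[lo]) / (Wstar[j] - Wstar[lo])
  omega_c <- exp(log(omegas[lo]) + frac * (log(omegas[j]) - log(omegas[lo])))
  omega_c / (2 * pi)
}

#' Shape scale from the cutoff frequency
#'
#' Solving \eqn{\exp(-(\sigma\omega_C)^2/2) = 1/\sqrt 2} for the Gaussian
#' amplitude model gives
#' \deqn{\sigma = \frac{\sqrt{\ln 2}}{2\pi F_C}.}
#'
#' @param fc cutoff frequency (Hz), positive; vectorised.
#' @return shape scale \eqn{\sigma} in seconds.
#' @export
#' @examples
#' sigma_from_cutoff(10)    # 0.0133 s
#' sigma_from_cutoff(26.3)  # 0.00504 s
sigma_from_cutoff <- function(fc) {
  if (any(fc <= 0)) stop("fc must be positive")
  sqrt(log(2)) / (2 * pi * fc)
}

#' Two-step acceptance of the Gaussian spectral fit
#'
#' Compares the frequency-normalized spectrum
#' \eqn{Z(\gamma) = W^*(\omega_C\gamma)} (relative frequency
#' \eqn{\gamma = \omega/\omega_C} on the log grid) with the Gaussian
#' amplitude model expressed in the same units,
#' \eqn{G(\gamma) = e^{-(\sigma\omega_C\gamma)^2/2} = 2^{-\gamma^2/2}},
#' which is anchored to the empirical spectrum at the cutoff:
#' \eqn{Z(1) = G(1) = 1/\sqrt 2} by construction.  The test is a
#' two-step procedure:
#' \enumerate{
#'   \item the fit is accepted if the mean square error over
#'     \eqn{\gamma[1] \dots \gamma[J] = 1} is below `t1`;
#'   \item a six-point window `MSE[J+i-2, J+i+3]` (indices inclusive)
#'     slides towards higher frequencies, one grid point per step, until
#'     it exceeds `t2`; the stop index \eqn{m} defines the boundary
#'     frequency \eqn{F_B = \gamma[J+m] F_C} and the extension ratio
#'     \eqn{\varepsilon = F_B / F_C}.
#' }
#' If the window never exceeds `t2` within the grid, \eqn{F_B} is capped
#' at the last grid point and flagged `grid_limited`.
#'
#' @param gamma relative-frequency grid (increasing, log-spaced; must
#'   bracket 1).
#' @param Z normalized empirical amplitudes on `gamma`.
#' @param fc cutoff frequency (Hz), used to express \eqn{F_B} in Hz.
#' @param t1 step-1 mean-square-error threshold.
#' @param t2 step-2 windowed mean-square-error threshold.
#' @return list with `accepted`, `fb` (Hz), `epsilon`, `grid_limited`,
#'   and `mse` (list with `step1`, the window series `window`, and the
#'   stop index `stop_index`).
#' @export
fit_acceptance <- function(gamma, Z, fc, t1 = 1e-4, t2 = 2e-3) {
  stopifnot(length(gamma) == length(Z), !is.unsorted(gamma))
  G <- 2^(-gamma^2 / 2)          # exp(-(sigma * omega_C * gamma)^2 / 2)
  J <- which.min(abs(gamma - 1))
  if (J < 3L || J > length(gamma) - 4L)
    stop("relative-frequency grid too short around gamma = 1")
  step1 <- mean((Z[1:J] - G[1:J])^2)
  accepted <- step1 < t1
  fb <- NA_real_; epsilon <- NA_real_; grid_limited <- FALSE
  window <- numeric(0); stop_index <- NA_integer_
  if (accepted) {
    i <- 1L
    repeat {
      lo <- J + i - 2L; hi <- J + i + 3L
      if (hi > length(gamma)) { grid_limited <- TRUE; stop_index <- i - 1L; break }
      mse_i <- mean((Z[lo:hi] - G[lo:hi])^2)
      window <- c(window, mse_i)
      if (mse_i > t2) { stop_index <- i; break }
      i <- i + 1L
    }
    b <- if (grid_limited) length(gamma) else J + stop_index
    epsilon <- gamma[b]
    fb <- epsilon * fc
  }
  list(accepted = accepted, fb = fb, epsilon = epsilon,
       grid_limited = grid_limited,
       mse = list(step1 = step1, window = window, stop_index = stop_index))
}

#' Slope of the linear phase model
#'
#' Fits the linear phase model \eqn{\varphi(\omega) = \beta\omega} to the
#' unwrapped empirical phase by least squares over the band
#' \eqn{[f_0, 1.4 F_C]}, where deviations from linearity are negligible.
#' By default the intercept is left free (robust to residual unwrapping
#' offsets) and only the slope is reported as \eqn{\beta};
#' `through_origin = TRUE` forces the zero intercept of the model.
#'
#' @param omegas angular frequencies (rad/s) of the phase samples.
#' @param phase unwrapped phase samples (radians).
#' @param fc cutoff frequency (Hz).
#' @param f0 lower band edge (Hz).
#' @param through_origin force a zero intercept.
#' @return slope \eqn{\beta} in seconds.
#' @export
phase_beta <- function(omegas, phase, fc, f0 = omegas[1] / (2 * pi),
                       through_origin = FALSE) {
  f <- omegas / (2 * pi)
  # tolerant band edges: grid points constructed to land exactly on the
  # edges must not drop out through floating-point jitter
  band <- f >= f0 * (1 - 1e-9) & f <= 1.4 * fc * (1 + 1e-9)
  if (sum(band) < 3L) stop("fewer than 3 phase samples in [f0, 1.4 Fc]")
  x <- omegas[band]; y <- phase[band]
  if (through_origin) sum(x * y) / sum(x * x)
  else unname(coef(lm(y ~ x))[2L])
}

#' Fit the half-wave-function model to one half-wave
#'
#' Full per-fragment pipeline: a pilot SBF pass locates the cutoff
#' frequency, the final log-spaced spectrum (100 points per decade,
#' starting at \eqn{F_C/100}) yields \eqn{\kappa}, \eqn{F_C} and
#' \eqn{\sigma}, the two-step acceptance test yields \eqn{F_B} and
#' \eqn{\varepsilon}, and a linear-scale phase pass yields \eqn{\beta}.
#'
#' @param hw a [half_wave()].
#' @param samples_per_decade log-grid density for the amplitude passes.
#' @param decades decades spanned above \eqn{F_C/100} by the final grid.
#' @param t1,t2 acceptance thresholds (see [fit_acceptance()]).
#' @param through_origin passed to [phase_beta()].
#' @return one-row data frame with columns `label, tau, kappa, sigma,
#'   beta, fc, fb, epsilon, accepted, grid_limited, n_samples`.
#' @export
fit_half_wave <- function(hw, samples_per_decade = 100L, decades = 3L,
                          t1 = 1e-4, t2 = 2e-3, through_origin = FALSE) {
  stopifnot(inherits(hw, "half_wave"))
  T <- hw$duration
  failed <- function() data.frame(
    label = hw$label, tau = hw$tau, kappa = NA_real_, sigma = NA_real_,
    beta = NA_real_, fc = NA_real_, fb = NA_real_, epsilon = NA_real_,
    accepted = FALSE, grid_limited = NA, n_samples = length(hw$samples),
    stringsAsFactors = FALSE)

  # pilot pass: coarse log grid from well below 1/T up past the Nyquist scale
  f_lo <- 0.01 / T
  n_dec <- max(3L, ceiling(log10((2 / hw$dt) / f_lo)))
  pilot <- finite_fourier(hw, make_log_grid(2 * pi * f_lo, 20L, n_dec))
  fc0 <- tryCatch({
    norm0 <- normalize_amplitude(pilot, polarity = hw$polarity)
    estimate_cutoff(pilot$omegas, norm0$Wstar)
  }, error = function(e) NA_real_)
  if (!is.finite(fc0)) return(failed())

  # final amplitude pass anchored at Fc/100
  grid <- make_log_grid(2 * pi * fc0 / 100, samples_per_decade, decades)
  spec <- finite_fourier(hw, grid)
  fc <- tryCatch({
    norm <- normalize_amplitude(spec, polarity = hw$polarity)
    estimate_cutoff(spec$omegas, norm$Wstar)
  }, error = function(e) NA_real_)
  if (!is.finite(fc)) return(failed())
  sigma <- sigma_from_cutoff(fc)
  acc <- fit_acceptance(spec$omegas / (2 * pi * fc), norm$Wstar, fc,
                        t1 = t1, t2 = t2)

  # phase pass on a natural-scale grid over [Fc/100, 1.4 Fc]
  f0 <- fc / 100
  pgrid <- make_linear_grid(2 * pi * f0, 2 * pi * (1.4 * fc - f0) / 199, 200L)
  pspec <- finite_fourier(hw, pgrid)
  # the phase of the raw fragment; polarity flips add pi which the free
  # intercept absorbs, the slope is polarity-invariant
  beta <- tryCatch(
    phase_beta(pspec$omegas, pspec$phase, fc, f0 = f0,
               through_origin = through_origin),
    error = function(e) NA_real_)

  data.frame(label = hw$label, tau = hw$tau, kappa = norm$kappa,
             sigma = sigma, beta = beta, fc = fc, fb = acc$fb,
             epsilon = acc$epsilon, accepted = acc$accepted,
             grid_limited = acc$grid_limited,
             n_samples = length(hw$samples), stringsAsFactors = FALSE)
}
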