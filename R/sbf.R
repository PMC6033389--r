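#' Closed-form kernels of the triangular basis function
#'
#' Finite cosine and sine Fourier integrals of the unit triangular basis
#' function \eqn{r(t) = 1 - t} on \eqn{[0, 1]}:
#' \deqn{R_C(\omega) = \frac{1 - \cos\omega}{\omega^2},\qquad
#'       R_S(\omega) = \frac{\omega - \sin\omega}{\omega^2}.}
#' For \eqn{|\omega| < 10^{-4}} the Taylor expansions
#' \eqn{R_C \approx 1/2 - \omega^2/24},
#' \eqn{R_S \approx \omega/6 - \omega^3/120} are used to avoid
#' catastrophic cancellation; \eqn{\omega = 0} returns the limits
#' \eqn{(1/2, 0)}.  \eqn{R_C} is even and \eqn{R_S} odd in \eqn{\omega}.
#'
#' @param omega dimensionless angular argument; vectorised.
#' @return list with numeric vectors `Rc` and `Rs`.
#' @export
#' @examples
#' tbf_kernels(pi)  # (2/pi^2, 1/pi)
tbf_kernels <- function(omega) {
  small <- abs(omega) < 1e-4
  Rc <- Rs <- numeric(length(omega))
  w <- omega[!small]
  Rc[!small] <- (1 - cos(w)) / w^2
  Rs[!small] <- (w - sin(w)) / w^2
  ws <- omega[small]
  Rc[small] <- 0.5 - ws^2 / 24
  Rs[small] <- ws / 6 - ws^3 / 120
  list(Rc = Rc, Rs = Rs)
}

#' Logarithmic frequency grid
#'
#' Geometric grid \eqn{\omega_i = \omega_0 C^{i-1}} with
#' \eqn{C = \exp(\ln 10 / N_D)}, i.e. `samples_per_decade` points per
#' decade, spanning `decades` decades (the end point of the last decade
#' is included).
#'
#' @param omega0 initial angular frequency (rad/s), positive.
#' @param samples_per_decade points per decade \eqn{N_D}.
#' @param decades number of decades spanned.
#' @return object of class `frequency_grid`: list with `omegas`,
#'   `scale = "log"` and the generating parameters.
#' @export
#' @examples
#' g <- make_log_grid(2 * pi, samples_per_decade = 100, decades = 2)
#' length(g$omegas)  # 201
make_log_grid <- function(omega0, samples_per_decade = 100L, decades) {
  stopifnot(omega0 > 0, samples_per_decade >= 1L, decades >= 1L)
  C <- exp(log(10) / samples_per_decade)
  i <- seq_len(decades * samples_per_decade + 1L)
  structure(list(omegas = omega0 * C^(i - 1), scale = "log",
                 omega0 = omega0, C = C, nd = samples_per_decade),
            class = "frequency_grid")
}

#' Linear frequency grid
#'
#' Natural-scale grid \eqn{\omega_i = \omega_0 + i\,\Delta\omega},
#' \eqn{i = 0, \dots, n - 1}; used for phase-function calculations.
#'
#' @param omega0 first angular frequency (rad/s), non-negative.
#' @param d_omega step (rad/s), positive.
#' @param n number of points.
#' @return a `frequency_grid` with `scale = "linear"`.
#' @export
make_linear_grid <- function(omega0, d_omega, n) {
  stopifnot(omega0 >= 0, d_omega > 0, n >= 2L)
  structure(list(omegas = omega0 + (0:(n - 1L)) * d_omega,
                 scale = "linear", omega0 = omega0, d_omega = d_omega),
            class = "frequency_grid")
}

#' Interpolation coefficients of the similar-basis-function expansion
#'
#' Decomposes the piecewise-linear interpolant of a half-wave into
#' triangular basis functions:
#' \deqn{h(t) = \sum_{i=0}^{N} a_i\,r(t/t_{i+1}),}
#' with local knots \eqn{t_i = i\Delta} (the fragment is shifted to start
#' at 0) and an auxiliary terminal knot \eqn{t_{N+1} = t_N + \Delta} so
#' that a non-zero last sample decays linearly to zero over one extra
#' step.  The coefficients follow from the decomposition of each hat
#' function into three TBFs,
#' \eqn{\vartheta_i(t) = \alpha_i r(t/t_{i+1}) - \beta_i r(t/t_i)
#'   + \gamma_i r(t/t_{i-1})} with
#' \eqn{\alpha_i = t_{i+1}/\Delta t_{i+1}},
#' \eqn{\beta_i = t_i(\Delta t_{i+1} + \Delta t_i)/(\Delta t_{i+1}\Delta t_i)},
#' \eqn{\gamma_i = t_{i-1}/\Delta t_i}, giving the explicit solution
#' \eqn{a_i = \alpha_i w_i - \beta_{i+1} w_{i+1} + \gamma_{i+2} w_{i+2}}
#' (with \eqn{w_{N+1} = w_{N+2} = 0}) of the interpolation system
#' \eqn{h(t_i) = w_i}, \eqn{i = 0, \dots, N}.
#'
#' @param half_wave a [half_wave()] with at least 3 samples (uniform
#'   spacing).
#' @return object of class `tbf_coefficients`: list with `a`
#'   (coefficients \eqn{a_0 \dots a_N}) and `knots`
#'   (\eqn{t_1 \dots t_{N+1}}, the right endpoints of the TBF supports).
#' @seealso [finite_fourier()]
#' @export
interpolation_coefficients <- function(half_wave) {
  stopifnot(inherits(half_wave, "half_wave"))
  w <- half_wave$samples
  if (length(w) < 3L) stop("need at least 3 samples")
  N <- length(w) - 1L                       # samples w_0 .. w_N
  dt <- half_wave$dt
  t <- (0:(N + 2L)) * dt                    # t_0 .. t_{N+2}
  wx <- c(w, 0, 0)                          # w_{N+1} = w_{N+2} = 0
  i <- 0:N
  alpha <- t[i + 2L] / dt                   # alpha_i = t_{i+1} / dt
  beta  <- t[i + 2L] * 2 / dt               # beta_{i+1} = 2 t_{i+1} / dt
  gamma <- t[i + 2L] / dt                   # gamma_{i+2} = t_{i+1} / dt
  a <- alpha * wx[i + 1L] - beta * wx[i + 2L] + gamma * wx[i + 3L]
  structure(list(a = a, knots = t[2:(N + 2L)]), class = "tbf_coefficients")
}

#' Evaluate the piecewise-linear SBF interpolant
#'
#' @param coefficients a `tbf_coefficients` object.
#' @param t evaluation times relative to the fragment start (s).
#' @return interpolant values \eqn{h(t)}.
#' @export
sbf_interpolant <- function(coefficients, t) {
  a <- coefficients$a; knots <- coefficients$knots
  out <- numeric(length(t))
  for (j in seq_along(a)) {
    u <- t / knots[j]
    out <- out + a[j] * ifelse(u >= 0 & u <= 1, 1 - u, 0)
  }
  out
}

#' Finite Fourier transform of a half-wave (SBF algorithm)
#'
#' Computes the finite cosine and sine Fourier transforms
#' \deqn{W_C(\omega) = \int_0^T w(t)\cos(\omega t)\,dt,\qquad
#'       W_S(\omega) = \int_0^T w(t)\sin(\omega t)\,dt}
#' of the piecewise-linear interpolant of a half-wave, using the
#' similarity theorem on the TBF expansion:
#' \eqn{W_C(\omega) = \sum_i a_i t_{i+1} R_C(t_{i+1}\omega)} and
#' likewise with \eqn{R_S}.  This Filon-type evaluation is exact for the
#' interpolant at any frequency, which makes it suitable for short
#' aperiodic fragments where FFT-based analysis suffers from leakage.
#'
#' The phase is \eqn{\delta(\omega) = \mathrm{atan2}(W_S, W_C)},
#' unwrapped along the grid, so a delayed positive pulse has
#' \eqn{\delta(\omega) \approx +\beta\omega}.
#'
#' @param half_wave a [half_wave()].
#' @param grid a `frequency_grid` ([make_log_grid()] /
#'   [make_linear_grid()]).
#' @return object of class `sbf_spectrum`: list with `grid`, `omegas`,
#'   `Wc`, `Ws`, `amplitude` (\eqn{\sqrt{W_C^2 + W_S^2}}, uV s) and
#'   `phase` (radians, unwrapped).
#' @export
finite_fourier <- function(half_wave, grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  cf <- interpolation_coefficients(half_wave)
  om <- grid$omegas
  Wc <- Ws <- numeric(length(om))
  for (j in seq_along(cf$a)) {
    tk <- cf$knots[j]
    kern <- tbf_kernels(tk * om)
    Wc <- Wc + cf$a[j] * tk * kern$Rc
    Ws <- Ws + cf$a[j] * tk * kern$Rs
  }
  phase <- signal::unwrap(atan2(Ws, Wc))
  # anchor the unwrapped branch so it starts in (-pi/2, pi/2]
  phase <- phase - 2 * pi * round(phase[1] / (2 * pi))
  structure(list(grid = grid, omegas = om, Wc = Wc, Ws = Ws,
                 amplitude = sqrt(Wc^2 + Ws^2), phase = phase,
                 coefficients = cf),
            class = "sbf_spectrum")
}

#' @export
print.sbf_spectrum <- function(x, ...) {
  cat(sprintf("sbf_spectrum: %d frequencies (%s scale), f in [%g, %g] Hz\n",
              length(x$omegas), x$grid$scale,
              min(x$omegas) / (2 * pi), max(x$omegas) / (2 * pi)))
  invisible(x)
}

#' @export
as.data.frame.sbf_spectrum <- function(x, ...) {
  data.frame(f = x$omegas / (2 * pi), omega = x$omegas, Wc = x$Wc,
             Ws = x$Ws, amplitude = x$amplitude, phase = x$phase)
}
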