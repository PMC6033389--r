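#' The half-wave function
#'
#' Evaluates the closed-form half-wave function (HWF)
#' \deqn{\psi(t) = (\sigma\sqrt{2\pi})^{-1}\left[e^{-(t-\beta)^2/2\sigma^2}
#'   - e^{-(t+\beta)^2/2\sigma^2}\right], \quad t \ge 0,}
#' and \eqn{\psi(t) = 0} for \eqn{t < 0}.  The HWF is the causal time-domain
#' counterpart of the characteristic function
#' \eqn{G(i\omega) = \exp\{-(\sigma\omega)^2/2 - i\beta\omega\}} and is the
#' universal component shape from which mass potentials are built.
#'
#' @param t time (s); vectorised.
#' @param sigma shape scale (s), positive.
#' @param beta delay parameter (s), positive.
#' @return numeric vector of \eqn{\psi(t)} values (1/s).
#' @seealso [hwf_via_sine_transform()], [hwf_ode_solve()],
#'   [hwf_reconstruct()], [characteristic_eval()]
#' @export
#' @examples
#' hwf_eval(1, sigma = 1, beta = 1)  # (1 - exp(-2)) / sqrt(2*pi)
hwf_eval <- function(t, sigma, beta) {
  stopifnot(sigma > 0, beta > 0)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  out[pos] <- (exp(-(tp - beta)^2 / (2 * sigma^2)) -
               exp(-(tp + beta)^2 / (2 * sigma^2))) / (sigma * sqrt(2 * pi))
  out
}

#' Primary and secondary HWF components
#'
#' The two Gaussian fragments whose difference forms the HWF:
#' \eqn{\psi_P(t) = e^{-(t-\beta)^2/2\sigma^2}},
#' \eqn{\psi_S(t) = e^{-(t+\beta)^2/2\sigma^2}} (without the
#' \eqn{(\sigma\sqrt{2\pi})^{-1}} prefactor).
#'
#' @inheritParams hwf_eval
#' @return a list with vectors `psi_p` and `psi_s`.
#' @export
hwf_components <- function(t, sigma, beta) {
  stopifnot(sigma > 0, beta > 0)
  list(psi_p = exp(-(t - beta)^2 / (2 * sigma^2)),
       psi_s = exp(-(t + beta)^2 / (2 * sigma^2)))
}

#' HWF via the sine transform of the imaginary spectral part
#'
#' Evaluates \deqn{\psi(t) = \frac{2}{\pi}\int_0^\infty
#'   e^{-(\sigma\omega)^2/2}\,\sin(\beta\omega)\,\sin(\omega t)\,d\omega}
#' by adaptive quadrature, truncating the integral where the Gaussian
#' envelope falls below `1e-12`.  The integral has the closed form
#' implemented by [hwf_eval()]; this route exists as an independent
#' numerical cross-check of the causal inversion.
#'
#' @inheritParams hwf_eval
#' @param t time (s), `t >= 0`; vectorised.
#' @return numeric vector of \eqn{\psi(t)} values.
#' @export
hwf_via_sine_transform <- function(t, sigma, beta) {
  stopifnot(sigma > 0, beta >= 0, all(t >= 0))
  omega_max <- sqrt(-2 * log(1e-12)) / sigma
  vapply(t, function(ti) {
    if (ti == 0 || beta == 0) return(0)
    (2 / pi) * integrate(
      function(w) exp(-(sigma * w)^2 / 2) * sin(beta * w) * sin(w * ti),
      lower = 0, upper = omega_max,
      rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 2000L)$value
  }, numeric(1))
}

#' Integrate the nonlinear macroscale system for the HWF
#'
#' Solves the non-autonomous system
#' \deqn{\frac{d\psi_P}{dt} = \frac{\beta - t}{\sigma^2}\,\psi_P,\qquad
#'       \frac{d\psi_S}{dt} = -\frac{\beta + t}{\sigma^2}\,\psi_S,}
#' (the primary rate changes sign at \eqn{t = \beta}, where \eqn{\psi_P}
#' peaks; the secondary component decays for all \eqn{t > 0}).
#' with \eqn{\psi = \psi_P - \psi_S}, using an adaptive high-order solver
#' (absolute/relative tolerance `1e-10`; the solutions are smooth).
#' With the natural initial condition
#' `psi0 = exp(-beta^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))` applied
#' to both components, the solution coincides with the closed form of
#' [hwf_eval()].
#'
#' @inheritParams hwf_eval
#' @param t_grid increasing time grid starting at 0 (s).
#' @param psi0 common initial value for \eqn{\psi_P(0)} and
#'   \eqn{\psi_S(0)}; defaults to the value matching [hwf_eval()].
#' @return data frame with columns `time`, `psi_p`, `psi_s`, `psi`.
#' @export
hwf_ode_solve <- function(sigma, beta, t_grid,
                          psi0 = exp(-beta^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))) {
  stopifnot(sigma > 0, beta > 0, t_grid[1] == 0, !is.unsorted(t_grid),
            psi0 > 0)
  deriv <- function(t, y, parms) {
    list(c((beta - t) / sigma^2 * y[1],
           -(beta + t) / sigma^2 * y[2]))
  }
  sol <- deSolve::ode(y = c(p = psi0, s = psi0), times = t_grid,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed; istate = ", attr(sol, "istate")[1])
  data.frame(time = sol[, "time"], psi_p = sol[, "p"], psi_s = sol[, "s"],
             psi = sol[, "p"] - sol[, "s"])
}

#' Characteristic function of a half-wave
#'
#' \deqn{G(i\omega) = \exp\{-(\sigma\omega)^2/2 - i\beta\omega\}.}
#' The modulus is the Gaussian amplitude-spectrum model, the argument the
#' linear phase model; \eqn{|G| = 1/\sqrt 2} at the cutoff
#' \eqn{\omega_C = \sqrt{\ln 2}/\sigma}.
#'
#' @param omega angular frequency (rad/s); vectorised.
#' @inheritParams hwf_eval
#' @return complex vector.
#' @export
characteristic_eval <- function(omega, sigma, beta) {
  stopifnot(sigma > 0, beta > 0)
  exp(complex(real = -(sigma * omega)^2 / 2, imaginary = -beta * omega))
}

#' Reconstruct a mass potential from HWF parameters
#'
#' Builds \deqn{e(t) = \sum_i \kappa_i\,\psi_i(t - \tau_i)} on a uniform
#' grid, each component evaluated with its own \eqn{(\sigma_i, \beta_i)}
#' and vanishing before its onset \eqn{\tau_i}.
#'
#' @param params data frame with columns `tau`, `kappa`, `sigma`, `beta`
#'   (see [hwf_table()]).
#' @param dt sampling interval (s).
#' @param duration record length (s).
#' @param t_start time of the first sample (s).
#' @return a [sampled_signal()] of length `floor(duration / dt) + 1`.
#' @export
#' @examples
#' ecg <- hwf_reconstruct(hwf_table("ECG"), dt = 0.001, duration = 0.8)
hwf_reconstruct <- function(params, dt, duration, t_start = 0) {
  validate_hwf_params(params)
  stopifnot(dt > 0, duration > dt)
  t <- seq(t_start, t_start + duration, by = dt)
  v <- numeric(length(t))
  for (i in seq_len(nrow(params)))
    v <- v + params$kappa[i] *
      hwf_eval(t - params$tau[i], params$sigma[i], params$beta[i])
  sampled_signal(v, dt = dt, t_start = t_start)
}
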