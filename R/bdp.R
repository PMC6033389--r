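#' Single-step transition probabilities of the particle populations
#'
#' Probabilities of a one-particle birth and death over one step of
#' length `dt` for a population of size `x`, under resting or transient
#' conditions.  With rates expressed through the half-wave-function
#' parameters:
#' \itemize{
#'   \item resting (both populations):
#'     \eqn{p_b = p_d = x\,\Delta\,\beta/\sigma^2};
#'   \item transient primary: \eqn{p_b = x\,\Delta\,\beta/\sigma^2},
#'     \eqn{p_d = x\,\Delta\,(i\Delta)/\sigma^2} with `i` the step index
#'     counted from the switch;
#'   \item transient secondary: births blocked (\eqn{p_b = 0}),
#'     \eqn{p_d = x\,\Delta\,(i\Delta + \beta)/\sigma^2}.
#' }
#'
#' @param x population size (non-negative integer).
#' @param step_index step index `i` since the transient switch.
#' @param dt step size \eqn{\Delta} (s).
#' @param sigma,beta half-wave-function parameters (s).
#' @param phase `"resting"` or `"transient"`.
#' @param population `"primary"` or `"secondary"`.
#' @return named numeric vector `c(p_birth, p_death)`.  An error is
#'   raised if either probability reaches 1 (the step size is too large
#'   for the one-jump-per-step regime).
#' @export
transition_probabilities <- function(x, step_index, dt, sigma, beta,
                                     phase = c("resting", "transient"),
                                     population = c("primary", "secondary")) {
  phase <- match.arg(phase)
  population <- match.arg(population)
  stopifnot(x >= 0, step_index >= 0, dt > 0, sigma > 0, beta >= 0)
  s2 <- sigma^2
  if (phase == "resting") {
    pb <- pd <- x * dt * beta / s2
  } else if (population == "primary") {
    pb <- x * dt * beta / s2
    pd <- x * dt^2 * step_index / s2
  } else {
    pb <- 0
    pd <- x * dt * (step_index * dt + beta) / s2
  }
  if (pb >= 1 || pd >= 1)
    stop("transition probability >= 1; decrease dt")
  c(p_birth = pb, p_death = pd)
}

#' Simulate the primary and secondary particle populations
#'
#' Monte-Carlo realisation of the two charged-particle populations as
#' non-homogeneous birth-death processes.  Both populations start at
#' `n0` and evolve under balanced resting probabilities for `t_rest`
#' seconds; at \eqn{t_0 = 0} the rules switch smoothly (current sizes
#' carry over) to the transient regime for `t_end` seconds, under the
#' probabilities of [transition_probabilities()].  Per step, a birth
#' occurs iff a fresh uniform draw falls below the birth probability,
#' and likewise for deaths; extinction is absorbing.
#'
#' Randomness comes from the R generator: call `set.seed()` (or pass
#' `seed`) for reproducible trajectories.  The default
#' \eqn{\Delta = 10^{-7}} s suits populations up to a few hundred
#' particles with the bundled parameter sets; the stepper aborts if
#' `p_birth + p_death` reaches 0.1 at any visited state.
#'
#' @param sigma,beta half-wave-function parameters (s).
#' @param n0 initial size of both populations.
#' @param dt step size \eqn{\Delta} (s).
#' @param t_rest resting-phase duration before the switch (s).
#' @param t_end transient-phase duration (s).
#' @param seed optional integer seed.
#' @param record_every record the state every this many steps (the
#'   switch-relative times are exact multiples of `dt`).
#' @return object of class `bdp_trajectory`: data frame with columns
#'   `time` (s, 0 at the switch), `xp`, `xs`, `xn` (`xp - xs`), plus
#'   attributes `n0`, `sigma`, `beta`, `dt`.
#' @seealso [expected_trajectory()], [normalized_net()],
#'   [residual_analysis()]
#' @export
bdp_simulate <- function(sigma, beta, n0 = 50L, dt = 1e-7,
                         t_rest = 0.01, t_end = 0.07, seed = NULL,
                         record_every = NULL) {
  stopifnot(sigma > 0, beta >= 0, n0 >= 1, dt > 0, t_rest >= 0, t_end > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_rest <- as.integer(round(t_rest / dt))
  n_trans <- as.integer(round(t_end / dt))
  if (is.null(record_every))
    record_every <- max(1L, as.integer((n_rest + n_trans) %/% 4000L))
  raw <- bdp_run_cpp(as.integer(n0), sigma, beta, dt, n_rest, n_trans,
                     as.integer(record_every))
  out <- data.frame(time = (raw$step - n_rest) * dt, xp = raw$xp,
                    xs = raw$xs, xn = raw$xp - raw$xs)
  structure(out, class = c("bdp_trajectory", "data.frame"),
            n0 = n0, sigma = sigma, beta = beta, dt = dt)
}

#' Largest step size respecting the probability bound
#'
#' Chooses \eqn{\Delta} so that `p_birth + p_death` stays safely below
#' 0.1 at the largest population size the transient is expected to
#' visit (the deterministic peak \eqn{N_0 e^{\beta^2/2\sigma^2}} with a
#' threefold stochastic margin), capped at `dt_max`.
#'
#' @inheritParams bdp_simulate
#' @param dt_max upper cap on the step (s).
#' @return step size in seconds.
#' @export
bdp_auto_dt <- function(sigma, beta, n0, t_end = 0.07, dt_max = 1e-7) {
  x_max <- 3 * n0 * exp(beta^2 / (2 * sigma^2))
  rate_max <- (t_end + 2 * beta) / sigma^2
  min(dt_max, 0.09 / (x_max * rate_max))
}

#' Expected normalized population trajectory
#'
#' Closed-form mean of the transient populations, from the exponential
#' of the integrated net rate with \eqn{e(0) = 1}:
#' \deqn{e_P(t) = \exp\{[\beta^2 - (t-\beta)^2]/2\sigma^2\},\qquad
#'       e_S(t) = \exp\{[\beta^2 - (t+\beta)^2]/2\sigma^2\}.}
#' These equal \eqn{\psi_P(t)/\psi_P(0)} and \eqn{\psi_S(t)/\psi_S(0)};
#' the primary mean peaks at \eqn{t = \beta} with value
#' \eqn{e^{\beta^2/2\sigma^2}}.
#'
#' @param sigma,beta half-wave-function parameters (s).
#' @param t times since the switch (s), `t >= 0`.
#' @param population `"primary"` or `"secondary"`.
#' @return numeric vector of normalized means (population mean is
#'   `n0 * expected_trajectory(...)`).
#' @export
expected_trajectory <- function(sigma, beta, t,
                                population = c("primary", "secondary")) {
  population <- match.arg(population)
  stopifnot(sigma > 0, beta > 0, all(t >= 0))
  if (population == "primary")
    exp((beta^2 - (t - beta)^2) / (2 * sigma^2))
  else
    exp((beta^2 - (t + beta)^2) / (2 * sigma^2))
}

#' Normalized net trajectory and its theoretical companion
#'
#' Scales the net particle count by the initial size,
#' \eqn{X_N^*(t) = X_N(t)/N_0}, and evaluates the matching normalized
#' half-wave function \eqn{\psi^*(t) = \psi(t)/\psi_0} with
#' \eqn{\psi_0 = \psi_P(0)\,(\sigma\sqrt{2\pi})^{-1}}, so the two are
#' directly comparable.
#'
#' @param trajectory a `bdp_trajectory` from [bdp_simulate()].
#' @return data frame with columns `time`, `xn_star` and `psi_star`
#'   (`psi_star` is `NA` before the switch).
#' @export
normalized_net <- function(trajectory) {
  stopifnot(inherits(trajectory, "bdp_trajectory"))
  n0 <- attr(trajectory, "n0")
  sigma <- attr(trajectory, "sigma"); beta <- attr(trajectory, "beta")
  t <- trajectory$time
  psi_star <- rep(NA_real_, length(t))
  pos <- t >= 0
  psi_star[pos] <- expected_trajectory(sigma, beta, t[pos], "primary") -
                   expected_trajectory(sigma, beta, t[pos], "secondary")
  data.frame(time = t, xn_star = trajectory$xn / n0, psi_star = psi_star)
}

#' Residuals between simulated and analytic normalized trajectories
#'
#' For each initial size, runs `trials` independent simulations and
#' averages, over trials, the mean absolute residual
#' \eqn{|\psi^*(t_k) - X_N^*(t_k)|} evaluated at `checkpoints`
#' equidistant times across the transient window.  Decreasing residuals
#' with growing \eqn{N_0} quantify the convergence of single
#' realisations to the deterministic half-wave function.
#'
#' @inheritParams bdp_simulate
#' @param n0_values initial population sizes to compare.
#' @param trials simulated trials per initial size.
#' @param checkpoints number of equidistant evaluation times in
#'   `(0, t_end]`.
#' @param dt step size; `NULL` selects [bdp_auto_dt()] per initial size.
#' @return data frame with columns `n0`, `mean_abs_residual`, `dt`.
#' @export
residual_analysis <- function(sigma, beta, n0_values = c(10, 50, 100, 500),
                              trials = 20L, checkpoints = 100L,
                              t_rest = 0.01, t_end = 0.07, dt = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  t_k <- seq(t_end / checkpoints, t_end, length.out = checkpoints)
  res <- vapply(n0_values, function(n0) {
    dt_i <- if (is.null(dt)) bdp_auto_dt(sigma, beta, n0, t_end) else dt
    per_trial <- vapply(seq_len(trials), function(tr) {
      traj <- bdp_simulate(sigma, beta, n0 = n0, dt = dt_i,
                           t_rest = t_rest, t_end = t_end)
      nn <- normalized_net(traj)
      xk <- approx(nn$time, nn$xn_star, xout = t_k, rule = 2)$y
      pk <- expected_trajectory(sigma, beta, t_k, "primary") -
            expected_trajectory(sigma, beta, t_k, "secondary")
      mean(abs(pk - xk))
    }, numeric(1))
    mean(per_trial)
  }, numeric(1))
  dts <- vapply(n0_values, function(n0)
    if (is.null(dt)) bdp_auto_dt(sigma, beta, n0, t_end) else dt, numeric(1))
  data.frame(n0 = n0_values, mean_abs_residual = res, dt = dts)
}
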