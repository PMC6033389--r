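#' Fit the half-wave-function model to a mass-potential record
#'
#' Runs the full analysis pipeline on a sampled record: adaptive
#' segmentation at zero-crossings and rectified-trace minima, removal of
#' fragments shorter than `min_samples`, per-fragment finite Fourier
#' transform (SBF algorithm), Gaussian amplitude-spectrum fit with the
#' two-step acceptance test, and linear phase fit.  The result is one
#' parameter row \eqn{(\tau, \kappa, \sigma, \beta, F_C, F_B,
#' \varepsilon)} per eligible half-wave, from which the record model
#' \eqn{e(t) = \sum_i \kappa_i \psi_i(t - \tau_i)} is reconstructed.
#'
#' @param signal a [sampled_signal()], or a numeric vector together with
#'   `dt`.
#' @param dt sampling interval (s) when `signal` is a plain vector.
#' @param min_samples minimum half-wave length in samples.
#' @param samples_per_decade density of the logarithmic frequency grid.
#' @param t1,t2 acceptance-test thresholds (see [fit_acceptance()]).
#' @param interior_only segment strictly between detected points,
#'   ignoring the record ends (see [extract_half_waves()]).
#' @param through_origin force the phase regression through the origin.
#' @return object of class `masswave`: list with the fitted parameter
#'   table (`coefficients`), the segmentation points (`points`), the
#'   half-waves (`half_waves`), the input `signal` and the `call`.
#' @seealso [coef.masswave()], [predict.masswave()], [plot.masswave()],
#'   [simulate.masswave()]
#' @export
#' @examples
#' fit <- masswave(make_fixture("ECG"))
#' coef(fit)
masswave <- function(signal, dt = NULL, min_samples = 8L,
                     samples_per_decade = 100L, t1 = 1e-4, t2 = 2e-3,
                     interior_only = FALSE, through_origin = FALSE) {
  if (!inherits(signal, "sampled_signal")) {
    if (is.null(dt)) stop("supply a sampled_signal or a vector with 'dt'")
    signal <- sampled_signal(signal, dt = dt)
  }
  points <- find_segmentation_points(signal)
  hws <- extract_half_waves(signal, points, interior_only = interior_only)
  hws <- filter_eligible(hws, min_samples = min_samples)
  if (length(hws) == 0L) stop("no eligible half-waves after filtering")
  rows <- lapply(hws, fit_half_wave,
                 samples_per_decade = samples_per_decade,
                 t1 = t1, t2 = t2, through_origin = through_origin)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(coefficients = tab, points = points, half_waves = hws,
                 signal = signal, call = match.call()),
            class = "masswave")
}

#' @export
print.masswave <- function(x, ...) {
  cat("Half-wave decomposition of a mass potential\n")
  cat(sprintf("  %d segmentation points, %d eligible half-waves, %d accepted fits\n",
              nrow(x$points), nrow(x$coefficients),
              sum(x$coefficients$accepted, na.rm = TRUE)))
  print(x$coefficients[, c("label", "tau", "kappa", "sigma", "beta",
                           "fc", "epsilon", "accepted")], digits = 4)
  invisible(x)
}

#' @export
summary.masswave <- function(object, ...) {
  tab <- object$coefficients
  res <- residuals(object)
  structure(list(coefficients = tab,
                 n_points = nrow(object$points),
                 n_half_waves = nrow(tab),
                 n_accepted = sum(tab$accepted, na.rm = TRUE),
                 epsilon = tab$epsilon[tab$accepted & !tab$grid_limited],
                 rmse = sqrt(mean(res^2)),
                 signal_sd = sd(object$signal$values)),
            class = "summary.masswave")
}

#' @export
print.summary.masswave <- function(x, ...) {
  cat("Half-wave decomposition of a mass potential\n\n")
  cat(sprintf("Segmentation points: %d; eligible half-waves: %d; accepted Gaussian fits: %d\n",
              x$n_points, x$n_half_waves, x$n_accepted))
  if (length(x$epsilon))
    cat(sprintf("Extension ratio epsilon: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$epsilon), min(x$epsilon), max(x$epsilon)))
  cat(sprintf("Reconstruction RMSE: %.4g uV (signal SD %.4g uV)\n\n",
              x$rmse, x$signal_sd))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fitted half-wave parameters
#'
#' @param object a fitted `masswave` model.
#' @param ... unused.
#' @return the parameter table: one row per eligible half-wave with
#'   columns `label, tau, kappa, sigma, beta, fc, fb, epsilon, accepted,
#'   grid_limited, n_samples`.
#' @export
coef.masswave <- function(object, ...) object$coefficients

#' Reconstruct the fitted record model
#'
#' Evaluates \eqn{e(t) = \sum_i \kappa_i \psi_i(t - \tau_i)} from the
#' accepted parameter rows, at the original sample times or at new
#' times.
#'
#' @param object a fitted `masswave` model.
#' @param newtimes optional vector of evaluation times (s); defaults to
#'   the sample times of the input record.
#' @param ... unused.
#' @return numeric vector of model values (uV).
#' @export
predict.masswave <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) newtimes <- signal_times(object$signal)
  tab <- object$coefficients
  ok <- !is.na(tab$kappa) & !is.na(tab$sigma) & !is.na(tab$beta)
  v <- numeric(length(newtimes))
  for (i in which(ok))
    v <- v + tab$kappa[i] *
      hwf_eval(newtimes - tab$tau[i], tab$sigma[i], tab$beta[i])
  v
}

#' @export
fitted.masswave <- function(object, ...) predict(object)

#' @export
residuals.masswave <- function(object, ...)
  object$signal$values - fitted(object)

#' Plot a fitted half-wave decomposition
#'
#' Overlays the reconstructed model (sum of fitted half-wave functions)
#' on the record and marks the segmentation points.
#'
#' @param x a fitted `masswave` model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.masswave <- function(x, ...) {
  t <- signal_times(x$signal)
  matplot(t, cbind(x$signal$values, fitted(x)), type = "l",
          lty = c(1, 1), col = c("black", "red"),
          xlab = "time (s)", ylab = "voltage (uV)", ...)
  abline(v = x$points$time, col = "steelblue", lty = 3)
  legend("topright", legend = c("record", "HWF model"),
         col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Simulate records from a fitted model
#'
#' Draws `nsim` synthetic records from the fitted model: the
#' reconstructed half-wave-function sum plus i.i.d. Gaussian noise with
#' the residual standard deviation.
#'
#' @param object a fitted `masswave` model.
#' @param nsim number of records.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with one column per simulated record, sample times
#'   as row order.
#' @export
simulate.masswave <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu <- fitted(object)
  s <- sd(residuals(object))
  out <- as.data.frame(replicate(nsim, mu + rnorm(length(mu), sd = s)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
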