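#' Empirical cumulative distribution curve
#'
#' Right-continuous step function \eqn{F(x) = \#\{values \le x\}/n},
#' returned as the sorted sample together with the cumulative fractions,
#' which is the form plotted when comparing extension-ratio samples
#' across modalities.
#'
#' @param sample non-empty numeric vector.
#' @return object of class `ecdf_curve`: list with `values` (sorted),
#'   `fractions` (non-decreasing, ending at 1) and `n`.
#' @export
ecdf_curve <- function(sample) {
  if (length(sample) == 0L) stop("empty sample")
  v <- sort(sample)
  structure(list(values = v, fractions = seq_along(v) / length(v),
                 n = length(v)),
            class = "ecdf_curve")
}

#' @export
print.ecdf_curve <- function(x, ...) {
  cat(sprintf("ecdf_curve: n = %d, support [%g, %g]\n",
              x$n, min(x$values), max(x$values)))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the D-statistic, the greatest vertical deviation
#' \eqn{D = \sup_x |F_1(x) - F_2(x)|} between the two empirical
#' cumulative distribution functions, evaluating both one-sided limits
#' at every pooled point (so tied and aligned steps are handled
#' exactly).  The null hypothesis of a common distribution is rejected
#' at level `alpha` when \eqn{D} reaches the asymptotic critical value
#' \deqn{D_{crit} = c(\alpha)\sqrt{\frac{n + m}{nm}},\qquad
#'       c(\alpha) = \sqrt{\tfrac12\ln(2/\alpha)},}
#' (\eqn{c(0.05) = 1.358}; at \eqn{n = m = 100} the critical value is
#' 0.192, i.e. 0.2 to one decimal).
#'
#' @param s1,s2 non-empty numeric samples.
#' @param alpha significance level.
#' @return object of class `ks_result`: list with `D`, `n`, `m`,
#'   `critical`, `alpha`, `reject`.
#' @export
#' @examples
#' ks_two_sample(rnorm(100), rnorm(100))
ks_two_sample <- function(s1, s2, alpha = 0.05) {
  if (length(s1) == 0L || length(s2) == 0L) stop("empty sample")
  n <- length(s1); m <- length(s2)
  pooled <- sort(unique(c(s1, s2)))
  F1 <- vapply(pooled, function(x) sum(s1 <= x), numeric(1)) / n
  F2 <- vapply(pooled, function(x) sum(s2 <= x), numeric(1)) / m
  # right limits at the pooled points ...
  D <- max(abs(F1 - F2))
  # ... and left limits (step alignment at ties)
  D <- max(D, abs(c(0, F1[-length(F1)]) - c(0, F2[-length(F2)])))
  critical <- sqrt(log(2 / alpha) / 2) * sqrt((n + m) / (n * m))
  structure(list(D = D, n = n, m = m, critical = critical, alpha = alpha,
                 reject = D >= critical),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f (n = %d, m = %d), critical %.4f at alpha = %g -> %s\n",
              x$D, x$n, x$m, x$critical, x$alpha,
              if (x$reject) "reject" else "do not reject"))
  invisible(x)
}

#' Pairwise KS comparison of extension-ratio samples
#'
#' Runs [ks_two_sample()] on every unordered pair of the named samples,
#' as done when testing whether the extension-ratio distributions of
#' EEG, ECG and EMG half-waves are statistically indistinguishable.
#'
#' @param samples named list of at least two numeric vectors.
#' @param alpha significance level.
#' @return data frame with one row per pair: `sample1, sample2, D, n,
#'   m, critical, reject`.
#' @export
compare_epsilon_sets <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2L,
            !is.null(names(samples)), all(nzchar(names(samples))))
  pairs <- utils::combn(names(samples), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    r <- ks_two_sample(samples[[a]], samples[[b]], alpha = alpha)
    data.frame(sample1 = a, sample2 = b, D = r$D, n = r$n, m = r$m,
               critical = r$critical, reject = r$reject,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
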