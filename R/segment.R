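#' Locate segmentation points of a record
#'
#' Scans the interior samples of a record and emits a segmentation point
#' at \eqn{t_m} when either predicate fires:
#' \itemize{
#'   \item zero-crossing: \eqn{(v_{m-1} \le 0} and \eqn{v_{m+1} > 0)} or
#'     \eqn{(v_{m-1} \ge 0} and \eqn{v_{m+1} < 0)};
#'   \item rectified minimum: \eqn{|v_{m-1}| \ge |v_m| \le |v_{m+1}|}.
#' }
#' A sample satisfying both is labelled `zero_crossing`.  Runs of
#' consecutive samples satisfying the minimum predicate (plateaus of
#' equal rectified value) yield one point at the leftmost index.  Both
#' predicates are symmetric under sign reversal of the record.
#'
#' @param signal a [sampled_signal()] with at least 3 samples.
#' @return data frame with columns `index` (1-based sample index),
#'   `time` (s) and `kind` (`"zero_crossing"` or `"abs_minimum"`),
#'   sorted by index.
#' @seealso [extract_half_waves()]
#' @export
find_segmentation_points <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  v <- signal$values
  n <- length(v)
  if (n < 3L) stop("signal too short to segment (need >= 3 samples)")
  m  <- 2:(n - 1)                       # interior samples
  vl <- v[m - 1]; vm <- v[m]; vr <- v[m + 1]
  zc <- (vl <= 0 & vr > 0) | (vl >= 0 & vr < 0)
  am <- abs(vl) >= abs(vm) & abs(vm) <= abs(vr)
  # collapse plateau runs of the minimum predicate to their leftmost index
  am_first <- am & !c(FALSE, am[-length(am)] & abs(vm[-length(vm)]) == abs(vm[-1]))
  keep <- zc | am_first
  kind <- ifelse(zc[keep], "zero_crossing", "abs_minimum")
  data.frame(index = m[keep], time = signal_times(signal)[m[keep]],
             kind = kind, stringsAsFactors = FALSE)
}

#' One empirical half-wave
#'
#' @param samples voltage samples of the fragment (uV).
#' @param dt sampling interval (s).
#' @param tau time of the first sample of the fragment (s).
#' @param label optional label.
#' @return object of class `half_wave` with fields `samples`, `dt`,
#'   `tau`, `duration` (`(length - 1) * dt`) and `polarity` (sign of the
#'   sample of largest magnitude).
#' @export
half_wave <- function(samples, dt, tau, label = NA_character_) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 2L, dt > 0)
  pol <- sign(samples[which.max(abs(samples))])
  if (pol == 0) pol <- 1
  structure(list(samples = samples, dt = dt, tau = tau,
                 duration = (length(samples) - 1L) * dt,
                 polarity = pol, label = label),
            class = "half_wave")
}

#' @export
print.half_wave <- function(x, ...) {
  cat(sprintf("half_wave: %d samples, tau = %g s, T = %g s, polarity %+d\n",
              length(x$samples), x$tau, x$duration, x$polarity))
  invisible(x)
}

#' Cut a record into half-waves at segmentation points
#'
#' Each adjacent pair of segmentation points delimits one half-wave
#' \eqn{w_i(t) = v(t + \tau_{i-1})} on \eqn{[0, T_i]},
#' \eqn{T_i = \tau_i - \tau_{i-1}}.  Interior points belong to both
#' neighbouring fragments (shared endpoints).  Unless
#' `interior_only = TRUE`, the first and last samples of the record act
#' as implicit segmentation points so the whole record is covered.
#'
#' @param signal a [sampled_signal()].
#' @param points data frame from [find_segmentation_points()] (columns
#'   `index`, `time`; sorted, in range).
#' @param interior_only if `TRUE`, only detected points are used and the
#'   record ends are not treated as boundaries.
#' @return list of [half_wave()] objects.
#' @export
extract_half_waves <- function(signal, points, interior_only = FALSE) {
  stopifnot(inherits(signal, "sampled_signal"))
  idx <- as.integer(points$index)
  n <- length(signal$values)
  if (any(idx < 1L | idx > n)) stop("segmentation index out of range")
  if (is.unsorted(idx, strictly = TRUE)) stop("segmentation points must be sorted")
  if (!interior_only) idx <- unique(c(1L, idx, n))
  if (length(idx) < 2L) stop("need at least 2 boundary points")
  tt <- signal_times(signal)
  lapply(seq_len(length(idx) - 1L), function(i) {
    span <- idx[i]:idx[i + 1L]
    half_wave(signal$values[span], dt = signal$dt, tau = tt[idx[i]],
              label = as.character(i))
  })
}

#' Drop half-waves with too few samples
#'
#' Short fragments carry too little information for a stable spectral
#' fit; the default keeps half-waves with at least 8 samples.
#'
#' @param half_waves list of [half_wave()] objects.
#' @param min_samples minimum sample count (inclusive).
#' @return filtered list.
#' @export
filter_eligible <- function(half_waves, min_samples = 8L) {
  Filter(function(hw) length(hw$samples) >= min_samples, half_waves)
}

#' Re-assemble a record from its half-waves
#'
#' Inverse of [extract_half_waves()]: concatenates fragments using a
#' left-open convention past the first fragment (shared endpoints are
#' counted once).  Used mainly as a consistency check.
#'
#' @param half_waves list of [half_wave()] objects covering a record span.
#' @return a [sampled_signal()] over the covered span.
#' @export
reassemble_half_waves <- function(half_waves) {
  stopifnot(length(half_waves) >= 1L)
  dt <- half_waves[[1L]]$dt
  vals <- half_waves[[1L]]$samples
  for (hw in half_waves[-1L]) {
    if (abs(hw$dt - dt) > 1e-12) stop("mixed sampling intervals")
    vals <- c(vals, hw$samples[-1L])
  }
  sampled_signal(vals, dt = dt, t_start = half_waves[[1L]]$tau)
}
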