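#' Uniformly sampled voltage trace
#'
#' Container for a single-channel record \eqn{v_m = v(t_m)} sampled on the
#' uniform grid \eqn{t_m = t_0 + m\Delta}.  Values are in microvolts,
#' times in seconds.
#'
#' @param values numeric vector of voltage samples (uV); at least 2,
#'   all finite.
#' @param dt sampling interval \eqn{\Delta} in seconds; positive scalar.
#' @param t_start time of the first sample (s).
#' @return An object of class `sampled_signal`: a list with elements
#'   `values`, `dt`, `t_start`.
#' @seealso [read_signal()], [write_signal()], [signal_times()]
#' @export
#' @examples
#' s <- sampled_signal(sin(seq(0, 2 * pi, length.out = 64)), dt = 0.001)
#' length(s$values)
sampled_signal <- function(values, dt, t_start = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a sampled signal needs at least 2 samples")
  if (!all(is.finite(values)))
    stop("signal values must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive scalar (seconds)")
  structure(list(values = values, dt = as.numeric(dt),
                 t_start = as.numeric(t_start)),
            class = "sampled_signal")
}

#' Sample times of a signal
#'
#' @param x a [sampled_signal()].
#' @return numeric vector `t_start + (0:(n-1)) * dt`.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t_start + (seq_along(x$values) - 1) * x$dt
}

#' @export
print.sampled_signal <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("sampled_signal: %d samples, dt = %g s (%g Hz), span [%g, %g] s\n",
              n, x$dt, 1 / x$dt, x$t_start, x$t_start + (n - 1) * x$dt))
  cat(sprintf("  range [%g, %g] uV\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.sampled_signal <- function(x, ...) {
  data.frame(time = signal_times(x), value = x$values)
}

#' Read a sampled signal from delimited text
#'
#' Accepts one- or two-column whitespace- or comma-delimited numeric text;
#' lines starting with `#` are treated as comments.  A two-column file is
#' read as (time, voltage) and must carry a strictly increasing uniform
#' time grid (relative tolerance `1e-9`); a one-column file holds voltages
#' only and requires `dt_override`.
#'
#' @param path file path.
#' @param dt_override sampling interval in seconds, used for one-column
#'   files (and checked against the grid of two-column files if given).
#' @return a [sampled_signal()].
#' @export
read_signal <- function(path, dt_override = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    read.table(path, header = FALSE, comment.char = "#",
               sep = "", colClasses = "numeric"),
    error = function(e) stop("malformed numeric text in '", path, "': ",
                             conditionMessage(e)))
  if (nrow(tab) == 0L) stop("empty signal file: ", path)
  if (ncol(tab) == 1L) {
    if (is.null(dt_override))
      stop("one-column file needs 'dt_override' (sampling interval, s)")
    return(sampled_signal(tab[[1L]], dt = dt_override))
  }
  if (ncol(tab) != 2L)
    stop("expected 1 or 2 columns, got ", ncol(tab))
  times <- tab[[1L]]
  steps <- diff(times)
  if (any(steps <= 0)) stop("time column must be strictly increasing")
  dt <- steps[1L]
  if (max(abs(steps - dt)) > 1e-9 * max(abs(dt), 1))
    stop("non-uniform time grid (relative tolerance 1e-9)")
  if (!is.null(dt_override)) dt <- dt_override
  sampled_signal(tab[[2L]], dt = dt, t_start = times[1L])
}

#' Write a sampled signal as two-column delimited text
#'
#' Writes `time value` pairs at full double precision, compatible with
#' [read_signal()].
#'
#' @param signal a [sampled_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "sampled_signal"))
  df <- as.data.frame(signal)
  lines <- sprintf("%.17g\t%.17g", df$time, df$value)
  writeLines(c("# time_s\tvalue_uV", lines), con = path)
  invisible(path)
}
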