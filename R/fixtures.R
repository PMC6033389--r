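#' Generate a synthetic mass-potential record
#'
#' Builds an EEG-, ECG- or EMG-like record as the sum of half-wave
#' functions with the bundled reference parameters ([hwf_table()]),
#' optionally adding i.i.d. Gaussian measurement noise.  Defaults emulate
#' the acquisition settings typical for each modality: 500 Hz sampling
#' for EEG, 1 kHz for ECG, 5 kHz for eye-blink EMG, and a duration
#' covering the last onset plus five shape widths,
#' `max(tau) + 5 * (sigma + beta)`.
#'
#' The noise-free fixture is deterministic; with `noise_sd > 0` the
#' result is reproducible under `seed`.
#'
#' @param record_kind one of `"EEG"`, `"ECG"`, `"EMG"`.
#' @param dt sampling interval (s); `NULL` for the per-kind default.
#' @param duration record length (s); `NULL` for the coverage default.
#' @param noise_sd standard deviation of additive white Gaussian noise
#'   (uV); 0 for a clean record.
#' @param seed integer seed used when `noise_sd > 0`.
#' @param params optional replacement parameter table (same columns as
#'   [hwf_table()]); used e.g. to generate single-component records.
#' @return a [sampled_signal()].
#' @export
#' @examples
#' eeg <- make_fixture("EEG")
#' emg <- make_fixture("EMG", noise_sd = 0.5, seed = 1)
make_fixture <- function(record_kind = c("EEG", "ECG", "EMG"),
                         dt = NULL, duration = NULL, noise_sd = 0,
                         seed = 1L, params = NULL) {
  record_kind <- match.arg(toupper(record_kind), c("EEG", "ECG", "EMG"))
  if (is.null(params)) params <- hwf_table(record_kind)
  validate_hwf_params(params)
  if (is.null(dt))
    dt <- switch(record_kind, EEG = 0.002, ECG = 0.001, EMG = 0.0002)
  if (is.null(duration))
    duration <- max(params$tau + 5 * (params$sigma + params$beta))
  if (duration < max(params$tau + 5 * (params$sigma + params$beta)))
    warning("duration does not cover max(tau) + 5*(sigma + beta); ",
            "late components will be truncated")
  sig <- hwf_reconstruct(params, dt = dt, duration = duration)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    sig$values <- sig$values + rnorm(length(sig$values), sd = noise_sd)
  }
  sig
}
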