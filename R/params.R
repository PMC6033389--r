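## Reference half-wave-function parameter sets for the three canonical
## mass-potential modalities.  Columns: onset tau (s), signed magnitude
## kappa (uV*s), shape scale sigma (s), delay beta (s), cutoff fc (Hz),
## extension ratio epsilon (dimensionless).
.hwf_tables <- list(
  EMG = data.frame(
    label = as.character(1:6),
    tau   = c(0.043, 0.0476, 0.051, 0.0526, 0.0552, 0.0594),
    kappa = c(-0.00078, 0.000751, 0.000158, 0.00172, -0.00314, 0.00163),
    sigma = c(0.00103, 0.000728, 0.000409, 0.00054, 0.000896, 0.00149),
    beta  = c(0.00245, 0.00159, 0.00081, 0.00141, 0.00174, 0.00305),
    fc    = c(129, 182, 331, 246, 148, 89),
    epsilon = c(1.74, 1.82, 2.04, 2.69, 1.74, 1.78),
    stringsAsFactors = FALSE),
  EEG = data.frame(
    label = as.character(1:10),
    tau   = c(0.04, 0.096, 0.156, 0.208, 0.248, 0.284, 0.352, 0.424, 0.464, 0.496),
    kappa = c(-0.619, 0.648, 0.822, 0.2, -0.166, 0.897, -0.923, 0.124, -0.0501, 0.553),
    sigma = c(0.0124, 0.0133, 0.0103, 0.00856, 0.00762, 0.0156, 0.0159, 0.00836, 0.0068, 0.0159),
    beta  = c(0.0286, 0.0262, 0.0210, 0.0181, 0.0164, 0.0327, 0.0346, 0.016, 0.016, 0.04),
    fc    = c(10.7, 10, 12.9, 15.5, 17.4, 8.51, 8.31, 15.8, 19.5, 8.32),
    epsilon = c(1.78, 1.74, 1.78, 1.55, 1.66, 1.62, 1.66, 2.34, 1.7, 1.82),
    stringsAsFactors = FALSE),
  ECG = data.frame(
    label = c("P", "Q", "R", "S", "T"),
    tau   = c(0.136, 0.308, 0.348, 0.375, 0.58),
    kappa = c(3.99, -3.91, 7.19, -4.62, 5.04),
    sigma = c(0.0205, 0.0096, 0.00504, 0.00836, 0.023),
    beta  = c(0.05, 0.0251, 0.0133, 0.0129, 0.0605),
    fc    = c(6.46, 13.8, 26.3, 15.8, 5.75),
    epsilon = c(1.86, 1.66, 1.7, 1.55, 2.29),
    stringsAsFactors = FALSE)
)

#' Built-in half-wave-function parameter tables
#'
#' Returns the bundled reference parameter set (onset `tau`, signed
#' magnitude `kappa`, shape scale `sigma`, delay `beta`, cutoff `fc`,
#' extension ratio `epsilon`) for one of the three canonical record
#' kinds.  These sets describe typical single-channel records: 6
#' half-waves for eye-blink EMG, 10 for EEG, and the P, Q, R, S, T
#' deflections for ECG.  All times are in seconds, `kappa` in uV*s.
#'
#' @param kind one of `"EEG"`, `"ECG"`, `"EMG"`.
#' @return a data frame with columns
#'   `label, tau, kappa, sigma, beta, fc, epsilon`.
#' @seealso [make_fixture()], [hwf_reconstruct()]
#' @export
#' @examples
#' hwf_table("ECG")
hwf_table <- function(kind = c("EEG", "ECG", "EMG")) {
  kind <- match.arg(toupper(kind), c("EEG", "ECG", "EMG"))
  .hwf_tables[[kind]]
}

validate_hwf_params <- function(params) {
  need <- c("tau", "kappa", "sigma", "beta")
  if (!all(need %in% names(params)))
    stop("parameter table must have columns ", paste(need, collapse = ", "))
  if (any(params$sigma <= 0)) stop("sigma must be positive")
  if (any(params$beta <= 0)) stop("beta must be positive")
  if (is.unsorted(params$tau)) stop("tau must be non-decreasing")
  invisible(params)
}

#' Read / write half-wave parameter tables
#'
#' CSV with header `label,tau,kappa,sigma,beta` and optional `fc`,
#' `epsilon` columns; `#` lines are comments.
#'
#' @param path file path.
#' @return `read_hwf_table` returns a validated data frame.
#' @export
read_hwf_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE)
  validate_hwf_params(tab)
  tab
}

#' @param params data frame as returned by [hwf_table()].
#' @rdname read_hwf_table
#' @export
write_hwf_table <- function(params, path) {
  validate_hwf_params(params)
  write.table(params, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
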