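# Equilibrium binding isotherm and the log-normal single-cell fluorescence
# observation model shared by the simulator and the inference machinery.

#' Binding curve parameters for one variant
#'
#' Parameterizes the equilibrium binding isotherm
#' \deqn{f(c) = A \frac{c}{c + K_D} + B,}
#' where \eqn{c} is the free antigen concentration, \eqn{K_D} the dissociation
#' constant, \eqn{A} the saturating fluorescence signal (proportional to the
#' number of functional antibodies displayed per cell) and \eqn{B} the
#' background fluorescence.
#'
#' @param kd Dissociation constant, molar. Must be > 0.
#' @param amplitude Saturating signal \eqn{A}, arbitrary fluorescence units,
#'   >= 0.
#' @param background Background fluorescence \eqn{B}, same units, >= 0.
#' @return An object of class `binding_params`.
#' @examples
#' p <- binding_params(kd = 10^-8.9, amplitude = 100, background = 10)
#' mean_fluorescence(p, conc = 10^-8.9)  # half-saturation: A/2 + B
#' @export
binding_params <- function(kd, amplitude, background) {
  stopifnot_scalar(kd, "kd", positive = TRUE)
  stopifnot_scalar(amplitude, "amplitude", nonneg = TRUE)
  stopifnot_scalar(background, "background", nonneg = TRUE)
  structure(list(kd = kd, amplitude = amplitude, background = background),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("Binding curve: KD = 10^%.2f M, A = %.3g, B = %.3g\n",
              log10(x$kd), x$amplitude, x$background))
  invisible(x)
}

#' Log-normal cell-fluorescence noise model
#'
#' Single-cell fluorescence is modeled as log-normal around the isotherm
#' value: \eqn{\log_{10} f_{cell} \sim N(\log_{10} f(c), \sigma^2)}, so the
#' isotherm value is the *median* cell fluorescence. The spread absorbs both
#' cell-to-cell variability in antibody display and flow-cytometer noise.
#'
#' @param log_sd Standard deviation of log10 single-cell fluorescence,
#'   log10-units. Must be > 0. The default 0.5 reproduces the roughly
#'   half-decade spread of yeast-display flow histograms.
#' @return An object of class `fluor_noise`.
#' @export
noise_model <- function(log_sd = 0.5) {
  stopifnot_scalar(log_sd, "log_sd", positive = TRUE)
  structure(list(log_sd = log_sd), class = "fluor_noise")
}

#' Dissociation-constant sensitivity window
#'
#' The affinity range within which a titration over the default concentration
#' ladder can resolve \eqn{K_D}. Estimates at the window edges are reported as
#' censored (lower/upper detection limit).
#'
#' @param kd_min Lower detection limit, molar (default `10^-9.5`).
#' @param kd_max Upper detection limit, molar (default `10^-5`).
#' @return An object of class `sensitivity_window`.
#' @export
sensitivity_window <- function(kd_min = 10^-9.5, kd_max = 10^-5) {
  stopifnot_scalar(kd_min, "kd_min", positive = TRUE)
  stopifnot_scalar(kd_max, "kd_max", positive = TRUE)
  if (kd_min >= kd_max) stop("kd_min must be < kd_max")
  structure(list(kd_min = kd_min, kd_max = kd_max),
            class = "sensitivity_window")
}

#' Median cell fluorescence at a given antigen concentration
#'
#' Evaluates the binding isotherm \eqn{f(c) = A c/(c + K_D) + B}.
#'
#' @param params A [binding_params()] object.
#' @param conc Antigen concentration(s), molar, >= 0.
#' @return Fluorescence value(s), same length as `conc`.
#' @export
mean_fluorescence <- function(params, conc) {
  stopifnot(inherits(params, "binding_params"))
  if (any(!is.finite(conc) | conc < 0))
    stop("'conc' must be nonnegative and finite")
  params$amplitude * conc / (conc + params$kd) + params$background
}

# log10 median fluorescence; -Inf when the median is exactly 0 (B = 0 and no
# binding signal), in which case all probability mass lands in the lowest bin.
log10_mean_fluorescence <- function(params, conc) {
  f <- mean_fluorescence(params, conc)
  ifelse(f > 0, log10(f), -Inf)
}

check_gates <- function(gates) {
  if (length(gates) == 0L) return(invisible(numeric(0)))
  if (any(!is.finite(gates) | gates <= 0))
    stop("gate boundaries must be finite and > 0")
  if (any(diff(gates) <= 0))
    stop("gate boundaries must be strictly increasing")
  invisible(gates)
}

# Core forward map: rows = log10 median fluorescence values, columns = bins.
# Gates (fluorescence units) tile the axis together with +/- infinity.
bin_prob_matrix <- function(log10_f, log_sd, gates) {
  n_bins <- length(gates) + 1L
  if (n_bins == 1L)
    return(matrix(1, nrow = length(log10_f), ncol = 1L))
  z <- outer(log10_f, log10(gates), function(f, g) (g - f) / log_sd)
  cum <- stats::pnorm(z)              # rows may contain -Inf medians: pnorm(Inf)=1
  cbind(cum[, 1L, drop = TRUE],
        if (n_bins > 2L) cum[, -1L, drop = FALSE] - cum[, -ncol(cum), drop = FALSE],
        1 - cum[, ncol(cum), drop = TRUE])
}

#' Sorting-bin probabilities for one variant at one concentration
#'
#' The probability that a cell carrying the given binding parameters lands in
#' each fluorescence bin: the log-normal mass (median equal to the isotherm
#' value, spread `log_sd`) between consecutive gate boundaries.
#'
#' @param params A [binding_params()] object.
#' @param noise A [noise_model()] object.
#' @param conc Antigen concentration, molar (scalar, >= 0).
#' @param gates Strictly increasing fluorescence boundaries; `length(gates)+1`
#'   bins. An empty vector means a single all-encompassing bin.
#' @return Probability vector over bins (sums to 1).
#' @seealso [mean_bin_number()]
#' @export
bin_probabilities <- function(params, noise, conc, gates) {
  stopifnot(inherits(params, "binding_params"), inherits(noise, "fluor_noise"))
  stopifnot_scalar(conc, "conc", nonneg = TRUE)
  check_gates(gates)
  drop(bin_prob_matrix(log10_mean_fluorescence(params, conc),
                       noise$log_sd, gates))
}

#' Mean bin number of a bin-probability (or bin-count) vector
#'
#' \eqn{\sum_b b\, p_b} with bins indexed 0, 1, ..., n-1 from the lowest
#' fluorescence gate upward; the sequencing-derived proxy for mean cellular
#' fluorescence.
#'
#' @param probabilities Probability vector over bins (must sum to 1 within
#'   `tol`).
#' @param tol Tolerance for the normalization check.
#' @return Mean bin number (dimensionless, in `[0, n_bins - 1]`).
#' @export
mean_bin_number <- function(probabilities, tol = 1e-6) {
  if (abs(sum(probabilities) - 1) > tol)
    stop("bin probabilities must sum to 1")
  sum((seq_along(probabilities) - 1) * probabilities)
}

# Row-wise mean bin number for count/probability matrices (not normalized).
mean_bin_rows <- function(m) {
  tot <- rowSums(m)
  as.vector(m %*% (seq_len(ncol(m)) - 1)) / ifelse(tot > 0, tot, NA_real_)
}
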