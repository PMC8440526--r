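#' Bin probabilities of a periodically excited exponential decay
#'
#' Computes the probability that a photon from a (multi-)exponential decay,
#' excited by a pulsed laser with repetition period `rep_period`, arrives in
#' each of `n_bins` equal-width TCSPC bins spanning `[0, rep_period)`.
#'
#' Under periodic excitation the steady-state arrival-time density on one
#' period is the wrapped exponential
#' \deqn{f(t) = \frac{e^{-t/\tau}}{\tau\,(1 - e^{-T/\tau})}, \quad t \in [0, T),}
#' which already contains the tails of all previous pulses (geometric sum).
#' Probabilities are exact bin integrals of this density, optionally
#' convolved circularly with a Gaussian instrument response of width
#' `irf_sigma`, then mixed with a uniform background component.
#'
#' @param lifetimes Decay lifetimes in ns (one per component).
#' @param amplitudes Fractional amplitudes, summing to 1.
#' @param rep_period Laser repetition period in ns (25 ns at 40 MHz).
#' @param n_bins Number of TCSPC bins.
#' @param irf_sigma Gaussian IRF standard deviation in ns; 0 disables.
#' @param background_fraction Fraction of photons arriving uniformly in time.
#'
#' @return Numeric vector of length `n_bins` summing to 1.
#' @export
decay_bin_probabilities <- function(lifetimes, amplitudes = rep(1 / length(lifetimes), length(lifetimes)),
                                    rep_period = 25, n_bins = 256,
                                    irf_sigma = 0, background_fraction = 0) {
  if (length(lifetimes) < 1L || any(!is.finite(lifetimes)) || any(lifetimes <= 0)) {
    abort("`lifetimes` must be positive and finite.",
          class = "osmofret_invalid_parameter")
  }
  if (length(amplitudes) != length(lifetimes) || any(amplitudes < 0) ||
      abs(sum(amplitudes) - 1) > 1e-8) {
    abort("`amplitudes` must be non-negative and sum to 1.",
          class = "osmofret_invalid_parameter")
  }
  assert_scalar_number(rep_period, "rep_period", lower = 0, strict_lower = TRUE)
  n_bins <- assert_count(n_bins, "n_bins", lower = 1L)
  assert_scalar_number(irf_sigma, "irf_sigma", lower = 0)
  assert_scalar_number(background_fraction, "background_fraction", lower = 0, upper = 1)

  edges <- seq(0, rep_period, length.out = n_bins + 1L)
  p <- numeric(n_bins)
  for (i in seq_along(lifetimes)) {
    tau <- lifetimes[i]
    norm <- 1 - exp(-rep_period / tau)
    comp <- (exp(-edges[-length(edges)] / tau) - exp(-edges[-1L] / tau)) / norm
    p <- p + amplitudes[i] * comp
  }
  if (irf_sigma > 0) {
    p <- circular_gaussian_smooth(p, sigma_bins = irf_sigma / (rep_period / n_bins))
  }
  p <- (1 - background_fraction) * p + background_fraction / n_bins
  p / sum(p)
}

# Circular convolution with a discretized Gaussian kernel (sigma in bins).
circular_gaussian_smooth <- function(p, sigma_bins) {
  n <- length(p)
  half <- min(n %/% 2L, ceiling(5 * sigma_bins))
  k <- exp(-((-half):half)^2 / (2 * sigma_bins^2))
  k <- k / sum(k)
  idx <- outer(seq_len(n), (-half):half, function(i, j) ((i + j - 1L) %% n) + 1L)
  as.vector(matrix(p[idx], nrow = n) %*% k)
}

#' Construct a TCSPC decay histogram
#'
#' A light container for binned photon-arrival counts: a tibble with columns
#' `bin_center_ns` and `counts`, carrying `rep_period` and `irf_sigma` as
#' attributes.
#'
#' @param counts Photon counts per bin (non-negative).
#' @param rep_period Repetition period in ns.
#' @param irf_sigma Gaussian IRF sigma in ns recorded with the acquisition.
#'
#' @return A `decay_histogram` tibble.
#' @export
decay_histogram <- function(counts, rep_period = 25, irf_sigma = 0) {
  assert_scalar_number(rep_period, "rep_period", lower = 0, strict_lower = TRUE)
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("`counts` must be finite and non-negative.",
          class = "osmofret_invalid_parameter")
  }
  n_bins <- length(counts)
  width <- rep_period / n_bins
  out <- tibble(
    bin_center_ns = (seq_len(n_bins) - 0.5) * width,
    counts = as.numeric(counts)
  )
  attr(out, "rep_period") <- rep_period
  attr(out, "irf_sigma") <- irf_sigma
  class(out) <- c("decay_histogram", class(out))
  out
}

rep_period_of <- function(decay) {
  rp <- attr(decay, "rep_period")
  if (is.null(rp)) abort("decay histogram lacks a `rep_period` attribute.",
                         class = "osmofret_invalid_parameter")
  rp
}
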