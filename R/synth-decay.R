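#' Ground truth for a synthetic TCSPC acquisition
#'
#' Bundles the parameters of a simulated photon-arrival experiment:
#' component lifetimes and amplitudes, the photon budget, repetition period
#' (25 ns, i.e. 40 MHz, by default), bin count, instrument response width
#' and uniform-background fraction.
#'
#' @param lifetimes Component lifetimes in ns.
#' @param amplitudes Fractional amplitudes summing to 1.
#' @param total_photons Total photons to distribute over the histogram.
#' @param rep_period Repetition period in ns.
#' @param n_bins Number of TCSPC bins.
#' @param irf_sigma Gaussian IRF sigma in ns (0 = ideal instrument).
#' @param background_fraction Fraction of uniformly arriving photons.
#' @param seed Integer seed; all randomness of [gen_decay()] flows from it.
#'
#' @return A `decay_truth` list.
#' @export
decay_truth <- function(lifetimes = 3.62, amplitudes = rep(1 / length(lifetimes), length(lifetimes)),
                        total_photons = 1e5, rep_period = 25, n_bins = 256,
                        irf_sigma = 0, background_fraction = 0, seed = 1L) {
  if (any(lifetimes <= 0)) {
    abort("`lifetimes` must be positive.", class = "osmofret_invalid_parameter")
  }
  assert_count(total_photons, "total_photons", lower = 0L)
  assert_scalar_number(rep_period, "rep_period", lower = 0, strict_lower = TRUE)
  assert_count(n_bins, "n_bins", lower = 1L)
  structure(
    list(lifetimes = lifetimes, amplitudes = amplitudes,
         total_photons = as.integer(total_photons), rep_period = rep_period,
         n_bins = as.integer(n_bins), irf_sigma = irf_sigma,
         background_fraction = background_fraction, seed = as.integer(seed)),
    class = "decay_truth"
  )
}

#' Simulate a TCSPC decay histogram
#'
#' Draws `total_photons` arrival times as a single multinomial sample over
#' the bin probabilities of the IRF-convolved, period-wrapped exponential
#' decay described by `truth`. Counts therefore sum to the requested photon
#' number exactly, and the draw is reproducible from `truth$seed`.
#'
#' @param truth A [decay_truth()] object.
#'
#' @return A [decay_histogram()] with integer counts.
#' @export
gen_decay <- function(truth) {
  stopifnot(inherits(truth, "decay_truth"))
  p <- decay_bin_probabilities(truth$lifetimes, truth$amplitudes,
                               truth$rep_period, truth$n_bins,
                               truth$irf_sigma, truth$background_fraction)
  counts <- with_local_seed(truth$seed, {
    as.vector(rmultinom(1L, size = truth$total_photons, prob = p))
  })
  decay_histogram(counts, rep_period = truth$rep_period,
                  irf_sigma = truth$irf_sigma)
}

#' Noiseless expected decay curve
#'
#' Returns the model curve of an acquisition described by `truth`: expected
#' (real-valued) counts per bin, i.e. `total_photons` times the bin
#' probabilities, with no counting noise. Useful as a noiseless input for
#' fitting and phasor computations.
#'
#' @inheritParams gen_decay
#' @return A [decay_histogram()] with real-valued expected counts.
#' @export
expected_decay <- function(truth) {
  stopifnot(inherits(truth, "decay_truth"))
  p <- decay_bin_probabilities(truth$lifetimes, truth$amplitudes,
                               truth$rep_period, truth$n_bins,
                               truth$irf_sigma, truth$background_fraction)
  decay_histogram(truth$total_photons * p, rep_period = truth$rep_period,
                  irf_sigma = truth$irf_sigma)
}
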