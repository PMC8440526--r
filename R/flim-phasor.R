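#' Phasor transform of a TCSPC decay
#'
#' Projects a decay histogram onto the phasor plane at the chosen harmonic
#' of the laser repetition rate:
#' \deqn{\omega = 2\pi h / T,\quad
#'       g = \frac{\sum_k c_k \cos(\omega t_k)}{\sum_k c_k},\quad
#'       s = \frac{\sum_k c_k \sin(\omega t_k)}{\sum_k c_k}.}
#' Noiseless mono-exponential decays land on the universal semicircle
#' `s^2 + (g - 1/2)^2 = 1/4`, with `g = 1/(1 + (\omega\tau)^2)` and
#' `s = \omega\tau g`; longer lifetimes shift points toward the left
#' (small `g`).
#'
#' @param decay A [decay_histogram()].
#' @param harmonic Harmonic of the repetition rate (default 1).
#'
#' @return A one-row tibble of class `phasor_point` with `g`, `s`, `omega`,
#'   `harmonic` and `total_counts`.
#' @export
phasor_transform <- function(decay, harmonic = 1L) {
  stopifnot(inherits(decay, "decay_histogram"))
  harmonic <- assert_count(harmonic, "harmonic", lower = 1L)
  total <- sum(decay$counts)
  if (total <= 0) {
    abort("decay histogram has zero total counts.",
          class = "osmofret_division_error")
  }
  rp <- rep_period_of(decay)
  omega <- 2 * pi * harmonic / rp
  t_k <- decay$bin_center_ns
  g <- sum(decay$counts * cos(omega * t_k)) / total
  s <- sum(decay$counts * sin(omega * t_k)) / total
  structure(
    tibble(g = g, s = s, omega = omega, harmonic = harmonic,
           total_counts = total),
    class = c("phasor_point", class(tibble())))
}

#' Closed-form phasor of a mono-exponential decay
#'
#' Reference coordinates `g = 1/(1+(omega*tau)^2)`, `s = omega*tau*g` for a
#' single-lifetime decay at angular frequency `omega` — the continuum limit
#' that [phasor_transform()] approaches as the bin width shrinks.
#'
#' @param tau Lifetime in ns.
#' @param rep_period Repetition period in ns.
#' @param harmonic Harmonic number.
#'
#' @return A tibble with `g` and `s`.
#' @export
phasor_monoexp <- function(tau, rep_period = 25, harmonic = 1L) {
  omega <- 2 * pi * harmonic / rep_period
  g <- 1 / (1 + (omega * tau)^2)
  tibble(g = g, s = omega * tau * g)
}
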