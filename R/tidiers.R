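# broom-style tidiers for the package's fitted objects.

#' Tidy a mono-exponential lifetime fit
#'
#' @param x A `lifetime_fit`.
#' @param ... Unused.
#' @return One row per model parameter with estimate and (for tau) a
#'   standard error.
#' @export
tidy.lifetime_fit <- function(x, ...) {
  tibble(
    term = c("tau", "amplitude", "background"),
    estimate = c(x$tau, x$amplitude, x$background),
    std.error = c(x$tau_stderr, NA_real_, NA_real_)
  )
}

#' One-row summary of a lifetime fit
#'
#' @inheritParams tidy.lifetime_fit
#' @export
glance.lifetime_fit <- function(x, ...) {
  tibble(tau = x$tau, tau_stderr = x$tau_stderr,
         reduced_chi2 = x$reduced_chi2, converged = x$converged,
         logLik = x$loglik, n_bins = x$n_bins, total_counts = x$total_counts)
}

#' Tidy a bleedthrough correction
#'
#' @param x A `bleedthrough_result`.
#' @param ... Unused.
#' @export
tidy.bleedthrough_result <- function(x, ...) {
  tibble(term = c("beta", "intercept"),
         estimate = c(x$beta, x$intercept))
}

#' Tidy a scramble selection
#'
#' @param x A `scramble_selection`.
#' @param ... Unused.
#' @return The candidate descriptor table with its `selected` flag.
#' @export
tidy.scramble_selection <- function(x, ...) x$candidates

#' One-row summary of a scramble selection
#'
#' @inheritParams tidy.scramble_selection
#' @export
glance.scramble_selection <- function(x, ...) {
  tibble(n_candidates = nrow(x$candidates), n_selected = nrow(x$selected),
         reference_kappa = x$reference$kappa,
         reference_helix = x$reference$helix_score)
}

#' Tidy a chain ensemble
#'
#' @param x A `chain_ensemble`.
#' @param ... Unused.
#' @return The snapshot-level Rg tibble.
#' @export
tidy.chain_ensemble <- function(x, ...) x$rg

#' One-row summary of a chain ensemble
#'
#' @inheritParams tidy.chain_ensemble
#' @export
glance.chain_ensemble <- function(x, ...) {
  tibble(mean_rg = mean(x$repeat_means), sd_rg = sd(x$repeat_means),
         n_repeats = length(x$repeat_means),
         acceptance_rate = mean(x$acceptance_rates),
         max_energy_drift = x$max_energy_drift,
         lambda = x$condition$lambda_repulsion)
}

#' One-row summary of a solution scan
#'
#' @param x A `scan_result`.
#' @param ... Unused.
#' @export
glance.scan_result <- function(x, ...) {
  tibble(n_conditions = nrow(x), sensitivity = attr(x, "sensitivity"),
         most_expanding_lambda = x$lambda[which.max(x$mean_rg)])
}
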