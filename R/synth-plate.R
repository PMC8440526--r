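#' Ground truth for a synthetic plate-reader experiment
#'
#' Describes an osmolarity dose response of the ratiometric FRET readout:
#' the expected raw DxAm/DxDm ratio at solute concentration `c` is
#' `baseline_ratio * (1 + slope_per_M * min(c, saturation_conc))`, a
#' linear-with-saturation model of the near-linear dose responses seen for
#' disordered-domain sensors. Noise is multiplicative lognormal with
#' coefficient of variation `noise_cv` on the ratio, plus an independent
#' common intensity factor shared by the channels of a well.
#'
#' @param baseline_ratio Expected raw ratio with no treatment.
#' @param slope_per_M Fractional ratio increase per molar of solute.
#' @param saturation_conc Concentration (M) above which the response stops
#'   growing; `Inf` for no saturation.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Wells per concentration (9 in a typical run).
#' @param concentrations Solute concentrations in M; 0 (the control group)
#'   is added if absent.
#' @param total_intensity Mean summed donor-excitation intensity per well (au).
#' @param response_tau_s Time constant (s) of the ramp toward the dose
#'   response when time points are simulated.
#' @param seed Integer seed; all randomness of [gen_plate_dataset()] flows
#'   from it.
#'
#' @return A `plate_truth` list.
#' @export
plate_truth <- function(baseline_ratio = 1, slope_per_M = 0.5,
                        saturation_conc = Inf, noise_cv = 0.05,
                        n_replicates = 9, concentrations = c(0, 0.25, 0.5, 0.75, 1),
                        total_intensity = 1000, response_tau_s = 300,
                        seed = 1L) {
  assert_scalar_number(baseline_ratio, "baseline_ratio", lower = 0, strict_lower = TRUE)
  assert_scalar_number(noise_cv, "noise_cv", lower = 0)
  assert_count(n_replicates, "n_replicates", lower = 1L)
  if (length(concentrations) == 0L) {
    abort("`concentrations` must be non-empty.",
          class = "osmofret_invalid_parameter")
  }
  if (any(concentrations < 0)) {
    abort("`concentrations` must be non-negative.",
          class = "osmofret_invalid_parameter")
  }
  if (!0 %in% concentrations) concentrations <- c(0, concentrations)
  structure(
    list(baseline_ratio = baseline_ratio, slope_per_M = slope_per_M,
         saturation_conc = saturation_conc, noise_cv = noise_cv,
         n_replicates = as.integer(n_replicates),
         concentrations = sort(unique(concentrations)),
         total_intensity = total_intensity, response_tau_s = response_tau_s,
         seed = as.integer(seed)),
    class = "plate_truth"
  )
}

#' Simulate a plate of ratiometric FRET well measurements
#'
#' Generates one `WellMeasurement` row per concentration, replicate and
#' (optionally) time point. The noisy raw ratio `R` is drawn lognormally
#' around the dose-response expectation, and the donor-excitation intensity
#' budget is split between the channels as `DxDm = I/(1+R)`,
#' `DxAm = I*R/(1+R)`, so the summed donor-excitation intensity is constant
#' in expectation and `DxAm/DxDm` recovers `R` exactly. Wells at 0 M carry
#' the treatment label `"control"`.
#'
#' @param truth A [plate_truth()] object.
#' @param timepoints Optional acquisition times in seconds (e.g. every 60 s);
#'   empty for a single endpoint read. When given, the dose term ramps as
#'   `1 - exp(-t/response_tau_s)`.
#'
#' @return A tibble with columns `well_id`, `DxDm`, `DxAm`, `AxAm`,
#'   `treatment`, `concentration_M`, `time_s`, `replicate` and the planted
#'   `true_ratio`.
#' @export
gen_plate_dataset <- function(truth, timepoints = numeric(0)) {
  stopifnot(inherits(truth, "plate_truth"))
  if (any(timepoints < 0)) {
    abort("`timepoints` must be non-negative.",
          class = "osmofret_invalid_parameter")
  }
  times <- if (length(timepoints) == 0L) NA_real_ else sort(unique(timepoints))

  design <- tidyr::expand_grid(
    concentration_M = truth$concentrations,
    replicate = seq_len(truth$n_replicates),
    time_s = times
  )
  dose <- truth$slope_per_M * pmin(design$concentration_M, truth$saturation_conc)
  ramp <- ifelse(is.na(design$time_s), 1,
                 1 - exp(-design$time_s / truth$response_tau_s))
  design$true_ratio <- truth$baseline_ratio * (1 + dose * ramp)

  n <- nrow(design)
  sdlog <- sqrt(log(1 + truth$noise_cv^2))
  out <- with_local_seed(truth$seed, {
    ratio_noise <- exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
    intensity_noise <- exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
    r <- design$true_ratio * ratio_noise
    i0 <- truth$total_intensity * intensity_noise
    dplyr::mutate(design,
      DxDm = i0 / (1 + r),
      DxAm = i0 * r / (1 + r),
      AxAm = 0.6 * i0
    )
  })
  out <- dplyr::mutate(out,
    well_id = sprintf("c%03d_r%02d%s",
                      match(.data$concentration_M, truth$concentrations),
                      .data$replicate,
                      ifelse(is.na(.data$time_s), "",
                             sprintf("_t%05d", as.integer(.data$time_s)))),
    treatment = ifelse(.data$concentration_M == 0, "control", "osmolyte")
  )
  dplyr::select(out, "well_id", "DxDm", "DxAm", "AxAm", "treatment",
                "concentration_M", "time_s", "replicate", "true_ratio")
}
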