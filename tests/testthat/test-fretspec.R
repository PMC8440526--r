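test_that("control normalization gives exact identities and forced arithmetic", {
  wells <- tibble::tibble(
    well_id = c("a", "b", "c"),
    DxDm = c(100, 120, 100), DxAm = c(160, 192, 200), AxAm = 1,
    treatment = c("control", "control", "NaCl"))
  out <- fret_ratio_normalize(wells)
  expect_equal(out$reference_mean[1], 1.6)
  expect_equal(out$normalized_ratio[3], 1.25)
  expect_equal(mean(out$normalized_ratio[out$treatment == "control"]), 1)

  # identity when control wells have DxAm = DxDm
  wells2 <- tibble::tibble(DxDm = c(5, 7, 3), DxAm = c(5, 7, 6),
                           treatment = c("control", "control", "t"))
  out2 <- fret_ratio_normalize(wells2)
  expect_equal(out2$normalized_ratio[1:2], c(1, 1))
})

test_that("normalization recovers the planted plate dose response", {
  tr <- plate_truth(baseline_ratio = 1, slope_per_M = 0.5, noise_cv = 0,
                    concentrations = c(0, 1), n_replicates = 3, seed = 1)
  out <- fret_ratio_normalize(gen_plate_dataset(tr))
  expect_equal(unique(out$normalized_ratio[out$concentration_M == 1]), 1.5)
})

test_that("ratios are invariant to joint channel rescaling and grouping works", {
  tr <- plate_truth(seed = 6)
  wells <- gen_plate_dataset(tr)
  scaled <- dplyr::mutate(wells, DxDm = DxDm * 7.3, DxAm = DxAm * 7.3,
                          AxAm = AxAm * 7.3)
  expect_equal(fret_ratio_normalize(wells)$normalized_ratio,
               fret_ratio_normalize(scaled)$normalized_ratio)
  # per-replicate grouping uses each replicate's own control mean
  grouped <- fret_ratio_normalize(wells, group = "replicate")
  ctrl <- dplyr::filter(grouped, treatment == "control")
  per_rep <- tapply(ctrl$normalized_ratio, ctrl$replicate, mean)
  expect_equal(as.vector(per_rep), rep(1, length(per_rep)))
})

test_that("ratio errors identify bad wells and missing controls", {
  wells <- tibble::tibble(well_id = c("w1", "w2"), DxDm = c(0, 10),
                          DxAm = c(1, 1), treatment = c("control", "x"))
  expect_error(fret_ratio_normalize(wells), regexp = "w1",
               class = "osmofret_division_error")
  wells2 <- tibble::tibble(DxDm = 1, DxAm = 1, treatment = "NaCl")
  expect_error(fret_ratio_normalize(wells2), class = "osmofret_reference_error")
})

test_that("spectrum normalization anchors at the nearest sample", {
  spec <- tibble::tibble(wavelength_nm = seq(460, 550, by = 5),
                         intensity = 2)
  spec$intensity[spec$wavelength_nm == 480] <- 4
  out <- normalize_spectrum(spec)
  expect_equal(out$intensity[out$wavelength_nm == 515], 1)
  expect_equal(out$intensity[out$wavelength_nm == 480], 2)
  # off-grid anchor snaps to nearest sample (514.6 -> 515)
  out2 <- normalize_spectrum(spec, anchor = 514.6)
  expect_equal(out2$intensity[out2$wavelength_nm == 515], 1)
  # flat spectrum becomes all ones
  flat <- tibble::tibble(wavelength_nm = seq(460, 550, 5), intensity = 3)
  expect_true(all(normalize_spectrum(flat)$intensity == 1))
  # zero anchor intensity errors
  z <- flat; z$intensity[z$wavelength_nm == 515] <- 0
  expect_error(normalize_spectrum(z), class = "osmofret_normalization_error")
})

test_that("band ratio uses inclusive bounds and responds to transfer efficiency", {
  flat <- tibble::tibble(wavelength_nm = 460:600, intensity = 1)
  expect_equal(band_ratio(flat), 101 / 40)
  donor_only <- tibble::tibble(wavelength_nm = 460:600,
                               intensity = as.numeric(460:600 <= 499))
  expect_equal(band_ratio(donor_only), 0)
  # higher planted E shifts emission into the acceptor band
  expect_gt(band_ratio(synthetic_spectrum(0.3)),
            band_ratio(synthetic_spectrum(0.1)))
  # ratio of a summed spectrum is bracketed by the component ratios
  a <- synthetic_spectrum(0.1); b <- synthetic_spectrum(0.5)
  ab <- a; ab$intensity <- a$intensity + b$intensity
  r <- sort(c(band_ratio(a), band_ratio(b)))
  expect_gte(band_ratio(ab), r[1])
  expect_lte(band_ratio(ab), r[2])
})

test_that("bleedthrough estimation is exact on noiseless data and robust to noise", {
  pb0 <- tibble::tibble(DxDm = seq(10, 100, 10), DxAm = 0.3 * seq(10, 100, 10))
  res0 <- bleedthrough_correct(pb0, beta = "estimate", photobleached_set = pb0)
  expect_equal(res0$beta, 0.3)
  expect_equal(res0$intercept, 0)
  expect_true(all(abs(res0$data$DxAm_corrected) < 1e-10))

  # beta = 0 is the identity
  d <- tibble::tibble(DxDm = 1:5, DxAm = 6:10)
  expect_equal(bleedthrough_correct(d, beta = 0)$data$DxAm_corrected, 6:10)

  # planted beta = 0.3 with 2% noise, 50 points -> within 0.01
  set.seed(42)
  dx <- runif(50, 50, 500)
  pb <- tibble::tibble(DxDm = dx, DxAm = 0.3 * dx * exp(rnorm(50, sd = 0.02)))
  res <- bleedthrough_correct(pb, beta = "estimate", photobleached_set = pb)
  expect_lt(abs(res$beta - 0.3), 0.01)

  expect_error(bleedthrough_correct(d, beta = "estimate",
                                    photobleached_set = pb0[1:2, ]),
               class = "osmofret_insufficient_data")
})

test_that("dose-response sensitivity is exact OLS with a sign dead-band", {
  res <- tibble::tibble(normalized_ratio = c(1.0, 1.1, 1.2, 1.3),
                        concentration_M = c(0, 0.5, 1.0, 1.5))
  s <- suppressWarnings(dose_response_sensitivity(res))
  expect_equal(s$slope, 0.2)
  expect_equal(s$direction, "compaction")

  flat <- tibble::tibble(normalized_ratio = rep(1, 4),
                         concentration_M = c(0, 0.5, 1, 1.5))
  s2 <- suppressWarnings(dose_response_sensitivity(flat))
  expect_equal(s2$slope, 0)
  expect_equal(s2$direction, "none")

  neg <- tibble::tibble(normalized_ratio = c(1.3, 1.2, 1.1, 1.0),
                        concentration_M = c(0, 0.5, 1, 1.5))
  expect_equal(suppressWarnings(dose_response_sensitivity(neg))$direction,
               "expansion")

  same <- tibble::tibble(normalized_ratio = 1:4, concentration_M = 1)
  expect_error(dose_response_sensitivity(same),
               class = "osmofret_degenerate_design")
})

test_that("sensitivity recovers the planted slope and ignores row order", {
  tr <- plate_truth(slope_per_M = 0.5, noise_cv = 0.05, n_replicates = 9,
                    concentrations = c(0, 0.25, 0.5, 0.75, 1), seed = 8)
  out <- fret_ratio_normalize(gen_plate_dataset(tr))
  s <- dose_response_sensitivity(out)
  expect_lt(abs(s$slope - 0.5), 0.05)
  shuffled <- out[sample(nrow(out)), ]
  expect_equal(dose_response_sensitivity(shuffled)$slope, s$slope)
})

test_that("loess smoothing is exact on constant and linear series", {
  d <- tibble::tibble(time_s = seq(0, 100, 10), normalized_ratio = 2)
  sm <- smooth_timecourse(d, span = 0.5)
  expect_equal(sm$smoothed, rep(2, nrow(d)))

  lin <- tibble::tibble(time_s = seq(0, 100, 10),
                        normalized_ratio = 1 + 0.01 * seq(0, 100, 10))
  sm2 <- smooth_timecourse(lin, span = 0.5)
  expect_equal(sm2$smoothed, lin$normalized_ratio, tolerance = 1e-10)

  expect_error(smooth_timecourse(lin, span = 0.05),
               class = "osmofret_span_error")
  expect_error(smooth_timecourse(lin[1:3, ]),
               class = "osmofret_invalid_parameter")
})

test_that("smoothed noisy step response tracks the truth within 2 noise SD", {
  tr <- plate_truth(baseline_ratio = 1, slope_per_M = 0.5, noise_cv = 0.03,
                    concentrations = c(0, 1), n_replicates = 1,
                    response_tau_s = 300, seed = 23)
  wells <- gen_plate_dataset(tr, timepoints = seq(0, 3000, 60))
  treated <- dplyr::filter(wells, concentration_M == 1)
  treated$obs <- treated$DxAm / treated$DxDm
  sm <- smooth_timecourse(treated, time = time_s, value = obs, span = 0.3)
  noise_sd <- 0.03 * mean(treated$true_ratio)
  interior <- seq_along(sm$time) > 3 & seq_along(sm$time) < nrow(sm) - 3
  frac <- mean(abs(sm$smoothed - treated$true_ratio)[interior] < 2 * noise_sd)
  expect_gte(frac, 0.9)
})
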