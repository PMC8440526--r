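#' Normalize an emission spectrum to an anchor wavelength
#'
#' Divides all intensities by the intensity at the sampled wavelength
#' nearest to `anchor` (ties break toward the lower wavelength), so the
#' anchor intensity becomes exactly 1. 515 nm is the conventional anchor
#' for cyan/yellow FRET pair emission scans.
#'
#' @param spec Data frame with `wavelength_nm` (strictly increasing) and
#'   `intensity` (non-negative) columns.
#' @param anchor Anchor wavelength in nm; must lie within the scanned range.
#'
#' @return The spectrum tibble with normalized intensities.
#' @export
normalize_spectrum <- function(spec, anchor = 515) {
  spec <- validate_spectrum(spec)
  wl <- spec$wavelength_nm
  if (anchor < min(wl) || anchor > max(wl)) {
    abort(sprintf("anchor %.1f nm is outside the scanned range [%.1f, %.1f].",
                  anchor, min(wl), max(wl)),
          class = "osmofret_invalid_parameter")
  }
  d <- abs(wl - anchor)
  idx <- which(d == min(d))[1]  # tie -> lower wavelength (first match)
  ref <- spec$intensity[idx]
  if (ref == 0) {
    abort(sprintf("intensity at the anchor sample (%.1f nm) is zero.", wl[idx]),
          class = "osmofret_normalization_error")
  }
  dplyr::mutate(spec, intensity = .data$intensity / ref)
}

#' Acceptor/donor emission band ratio
#'
#' Ratio of summed sampled intensities inside the acceptor band to those
#' inside the donor band, both bands inclusive at their bounds (the 500-600
#' over 460-499 nm convention for cyan/yellow pairs).
#'
#' @param spec Spectrum data frame (`wavelength_nm`, `intensity`).
#' @param acceptor_band,donor_band Inclusive `[low, high]` bounds in nm.
#'
#' @return A single dimensionless ratio.
#' @export
band_ratio <- function(spec, acceptor_band = c(500, 600),
                       donor_band = c(460, 499)) {
  spec <- validate_spectrum(spec)
  in_band <- function(b) spec$wavelength_nm >= b[1] & spec$wavelength_nm <= b[2]
  don <- in_band(donor_band)
  acc <- in_band(acceptor_band)
  if (!any(don)) {
    abort("the spectrum has no samples inside the donor band.",
          class = "osmofret_invalid_parameter")
  }
  den <- sum(spec$intensity[don])
  if (den == 0) {
    abort("donor-band intensity sum is zero; ratio undefined.",
          class = "osmofret_division_error")
  }
  sum(spec$intensity[acc]) / den
}

#' Donor bleedthrough estimation and correction
#'
#' Estimates the donor-into-acceptor-channel bleedthrough coefficient
#' `beta` as the least-squares slope of `DxAm ~ DxDm` on an
#' acceptor-photobleached dataset (where all sensitized emission is pure
#' bleedthrough), then subtracts `beta * DxDm` from `DxAm`, flooring at
#' zero. The regression fits an intercept (reported as residual
#' background) but only the slope is applied.
#'
#' @param data Data frame with `DxDm` and `DxAm` columns to correct.
#' @param beta Either a known bleedthrough fraction or `"estimate"`.
#' @param photobleached_set Data frame of `DxDm`, `DxAm` measurements with
#'   the acceptor photobleached; required when `beta = "estimate"` (at
#'   least 3 points).
#'
#' @return A list of class `bleedthrough_result`: `data` (corrected tibble
#'   with `DxAm_corrected`), `beta`, and `intercept` (`NA` when `beta` was
#'   supplied).
#' @export
bleedthrough_correct <- function(data, beta = "estimate",
                                 photobleached_set = NULL) {
  data <- as_tibble(data)
  assert_columns(data, c("DxDm", "DxAm"), "`data`")
  intercept <- NA_real_
  if (identical(beta, "estimate")) {
    if (is.null(photobleached_set)) {
      abort("`photobleached_set` is required to estimate beta.",
            class = "osmofret_insufficient_data")
    }
    pb <- as_tibble(photobleached_set)
    assert_columns(pb, c("DxDm", "DxAm"), "`photobleached_set`")
    if (nrow(pb) < 3L) {
      abort("at least 3 photobleached points are needed to estimate beta.",
            class = "osmofret_insufficient_data")
    }
    fit <- lm(DxAm ~ DxDm, data = pb)
    beta <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
  } else {
    assert_scalar_number(beta, "beta", lower = 0)
  }
  corrected <- dplyr::mutate(
    data, DxAm_corrected = pmax(.data$DxAm - beta * .data$DxDm, 0))
  structure(list(data = corrected, beta = beta, intercept = intercept),
            class = "bleedthrough_result")
}

#' @export
print.bleedthrough_result <- function(x, ...) {
  cat(sprintf("<bleedthrough_result> beta = %.4f%s, %d rows corrected\n",
              x$beta,
              if (is.na(x$intercept)) "" else sprintf(" (intercept %.3g)", x$intercept),
              nrow(x$data)))
  invisible(x)
}

validate_spectrum <- function(spec) {
  spec <- as_tibble(spec)
  assert_columns(spec, c("wavelength_nm", "intensity"), "`spec`")
  wl <- spec$wavelength_nm
  if (length(wl) < 2L || any(diff(wl) <= 0)) {
    abort("`wavelength_nm` must be strictly increasing.",
          class = "osmofret_invalid_parameter")
  }
  if (any(spec$intensity < 0)) {
    abort("spectrum intensities must be non-negative.",
          class = "osmofret_invalid_parameter")
  }
  spec
}
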