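# File-format interfaces: TIFF stacks with JSON sidecars, CSV tables,
# decay histograms, FASTA sequences.

#' Write a cell stack as a multi-page TIFF with a JSON sidecar
#'
#' One 32-bit float page per channel in the order DxDm, DxAm, AxAm
#' (then lifetime, if present); the channel order, pixel size and intensity
#' scale are recorded in `<path>.json`.
#'
#' @param stack A [cell_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "cell_stack"))
  chans <- stack[channel_names()]
  if (!is.null(stack$lifetime)) {
    life <- stack$lifetime
    life[is.na(life)] <- 0
    chans <- c(chans, list(lifetime = life))
  }
  scale <- max(1, max(vapply(chans, max, 0)))
  pages <- lapply(chans, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(channels = names(chans), pixel_size_um = stack$pixel_size,
         intensity_scale = scale, lifetime_na_as_zero = !is.null(stack$lifetime)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a cell stack written by [write_stack()]
#'
#' @param path TIFF path with an adjacent `<path>.json` sidecar.
#' @return A [cell_stack()].
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(m) m * meta$intensity_scale)
  names(pages) <- meta$channels
  life <- pages$lifetime
  if (!is.null(life) && isTRUE(meta$lifetime_na_as_zero)) life[life == 0] <- NA
  cell_stack(DxDm = pages$DxDm, DxAm = pages$DxAm, AxAm = pages$AxAm,
             lifetime = life, pixel_size = meta$pixel_size_um)
}

#' Read/write plate-reader well tables
#'
#' CSV with the documented columns `well_id`, `DxDm`, `DxAm`, `AxAm`,
#' `treatment`, `concentration_M`, `time_s`, `replicate`.
#'
#' @param path CSV path.
#' @return A tibble of well measurements.
#' @export
read_plate_csv <- function(path) {
  wells <- readr::read_csv(path, show_col_types = FALSE)
  assert_columns(wells, c("DxDm", "DxAm", "AxAm", "treatment"), "plate CSV")
  wells
}

#' @rdname read_plate_csv
#' @param wells Tibble of well measurements.
#' @export
write_plate_csv <- function(wells, path) {
  readr::write_csv(wells, path)
  invisible(path)
}

#' Read/write emission spectra
#'
#' Two-column CSV: `wavelength_nm`, `intensity`.
#'
#' @param path CSV path.
#' @export
read_spectrum_csv <- function(path) {
  validate_spectrum(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_spectrum_csv
#' @param spec Spectrum tibble.
#' @export
write_spectrum_csv <- function(spec, path) {
  readr::write_csv(validate_spectrum(spec), path)
  invisible(path)
}

#' Read/write decay histograms
#'
#' CSV body (`bin_center_ns`, `counts`) with acquisition metadata
#' (`rep_period_ns`, `irf_sigma_ns`) in a JSON sidecar.
#'
#' @param decay A [decay_histogram()].
#' @param path CSV path.
#' @export
write_decay_csv <- function(decay, path) {
  stopifnot(inherits(decay, "decay_histogram"))
  readr::write_csv(as_tibble(decay), path)
  jsonlite::write_json(
    list(rep_period_ns = rep_period_of(decay),
         irf_sigma_ns = attr(decay, "irf_sigma") %||% 0),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  body <- readr::read_csv(path, show_col_types = FALSE)
  decay_histogram(body$counts, rep_period = meta$rep_period_ns,
                  irf_sigma = meta$irf_sigma_ns)
}

#' Read/write protein sequences as FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' @rdname read_fasta_sequences
#' @param sequences Named character vector.
#' @export
write_fasta_sequences <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
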