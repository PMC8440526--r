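#' Z-projection and background subtraction of an image stack
#'
#' Sums each channel over its z-planes and subtracts a per-channel
#' background: either the mean intensity inside a rectangular background
#' ROI, or (default) a low percentile of the summed channel. Negative
#' pixels are floored at zero.
#'
#' @param raw A [cell_stack()] (channels may be 3-D arrays).
#' @param background Either a list `list(x0, y0, x1, y1)` giving an
#'   inclusive rectangular ROI (pixel indices), a percentile in `[0, 100]`
#'   used per channel (default 5), or `NULL` for no subtraction.
#'
#' @return A single-plane [cell_stack()] with backgrounds removed.
#' @export
preprocess_stack <- function(raw, background = 5) {
  stopifnot(inherits(raw, "cell_stack"))
  zsum <- function(ch) if (length(dim(ch)) == 3L) apply(ch, c(1, 2), sum) else ch
  chans <- lapply(raw[channel_names()], zsum)
  dims <- dim(chans[[1]])

  bg_of <- function(ch) {
    if (is.null(background)) {
      0
    } else if (is.list(background)) {
      b <- background
      if (b$x0 < 1 || b$y0 < 1 || b$x1 > dims[2] || b$y1 > dims[1] ||
          b$x0 > b$x1 || b$y0 > b$y1) {
        abort("background ROI falls outside the image.",
              class = "osmofret_bounds_error")
      }
      mean(ch[b$y0:b$y1, b$x0:b$x1])
    } else {
      assert_scalar_number(background, "background", lower = 0, upper = 100)
      as.numeric(quantile(ch, background / 100))
    }
  }
  corrected <- lapply(chans, function(ch) pmax(ch - bg_of(ch), 0))
  cell_stack(DxDm = corrected$DxDm, DxAm = corrected$DxAm,
             AxAm = corrected$AxAm, lifetime = raw$lifetime,
             pixel_size = raw$pixel_size)
}

#' Ratiometric FRET image with an acceptor-channel mask
#'
#' Implements the standard ratiometric recipe: Gaussian-blur all channels
#' (separable convolution, kernel radius `ceil(3*sigma)`, reflected
#' boundary), build a binary mask by thresholding the blurred AxAm channel
#' (Otsu by default, or a manual threshold), and form
#' `ratio = blurred DxAm / blurred DxDm` inside the mask and 0 outside.
#' The mask is stored as \{0, 1\}; dividing an 8-bit \{0, 255\} mask by 255
#' is the same operation. Masked pixels with zero DxDm are set to 0 and
#' counted in a warning.
#'
#' @param stack A preprocessed single-plane [cell_stack()].
#' @param blur_sigma Gaussian blur sigma in pixels (default 1).
#' @param mask_threshold `"otsu"` or a numeric threshold on blurred AxAm.
#'
#' @return A list of class `ratio_image`: `ratio` (matrix), `mask`
#'   (\{0,1\} matrix), `threshold`, and `n_zero_dxdm`.
#' @export
ratiometric_image <- function(stack, blur_sigma = 1, mask_threshold = "otsu") {
  stopifnot(inherits(stack, "cell_stack"))
  blur <- lapply(stack[channel_names()],
                 gaussian_blur, sigma = blur_sigma)
  thr <- if (identical(mask_threshold, "otsu")) {
    otsu_threshold(blur$AxAm)
  } else {
    assert_scalar_number(mask_threshold, "mask_threshold")
    mask_threshold
  }
  mask <- (blur$AxAm > thr) * 1
  zero_div <- mask == 1 & blur$DxDm == 0
  n_zero <- sum(zero_div)
  if (n_zero > 0) {
    warn(sprintf("%d masked pixel(s) had zero DxDm and were set to 0.", n_zero))
  }
  ratio <- matrix(0, nrow(mask), ncol(mask))
  ok <- mask == 1 & !zero_div
  ratio[ok] <- blur$DxAm[ok] / blur$DxDm[ok]
  structure(list(ratio = ratio, mask = mask, threshold = thr,
                 n_zero_dxdm = n_zero),
            class = "ratio_image")
}

#' Separable Gaussian blur with reflected boundaries
#'
#' The blur used by [ratiometric_image()]: a discretized Gaussian kernel of
#' radius `ceil(3*sigma)`, normalized to sum 1, applied along rows then
#' columns with edge reflection. Pinned explicitly so the full ratiometric
#' recipe is reproducible from its description alone.
#'
#' @param x Numeric matrix.
#' @param sigma Kernel standard deviation in pixels; 0 returns `x`.
#'
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(x, sigma = 1) {
  if (sigma == 0) return(x)
  assert_scalar_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect_index <- function(i, n) {
    # reflect around the edges: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  conv_cols <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in (-r):r) {
      idx <- reflect_index(seq_len(n) + j, n)
      out <- out + k[j + r + 1L] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(x))))
}

# Otsu threshold via EBImage on a unit-scaled copy.
otsu_threshold <- function(x) {
  mx <- max(x)
  if (mx == 0) return(0)
  EBImage::otsu(EBImage::Image(x / mx), range = c(0, 1)) * mx
}

#' Segment cells from the acceptor-excitation channel
#'
#' Automatic stand-in for manual ROI selection: Otsu-threshold the blurred
#' AxAm channel, fill holes (vacuoles must stay inside their cell), remove
#' objects below `min_area`, and split touching cells by a
#' distance-transform watershed. An empty image yields zero labels.
#'
#' @param stack A preprocessed [cell_stack()].
#' @param min_area Minimum object area in px^2.
#' @param blur_sigma Blur applied to AxAm before thresholding.
#'
#' @return An integer label matrix (0 = background).
#' @export
segment_cells <- function(stack, min_area = 50, blur_sigma = 1) {
  stopifnot(inherits(stack, "cell_stack"))
  ax <- gaussian_blur(stack$AxAm, blur_sigma)
  thr <- otsu_threshold(ax)
  mask <- EBImage::Image(ax > thr)
  if (sum(mask) == 0) return(matrix(0L, nrow(stack$AxAm), ncol(stack$AxAm)))
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  lab <- matrix(as.integer(EBImage::imageData(labels)),
                nrow(stack$AxAm), ncol(stack$AxAm))
  # drop small objects, then relabel compactly
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0L] <- relabel[lab[lab > 0L]]
  lab
}

#' Per-cell vacuolar-ratio and intensity statistics
#'
#' For every labelled cell, the vacuole is the largest connected region of
#' pixels darker than `theta` times the cell's median AxAm intensity that
#' does not touch the cell boundary (so off-cell darkness is never mistaken
#' for a vacuole); `vacuolar_ratio = vacuole_area / cell_area`, 0 when no
#' region qualifies. Mean lifetime and mean DxAm/DxDm ratio are computed
#' over cytoplasm pixels (cell minus vacuole).
#'
#' @param stack A preprocessed [cell_stack()].
#' @param labels Integer label matrix from [segment_cells()] or ground
#'   truth.
#' @param lifetime Optional lifetime image; defaults to `stack$lifetime`.
#' @param theta Vacuole darkness threshold relative to the cell median.
#'
#' @return A tibble with one `CellRecord` row per cell: `cell_id`,
#'   `cell_area`, `vacuole_area`, `vacuolar_ratio`, `mean_lifetime`,
#'   `mean_ratio`.
#' @export
vacuolar_ratio_stats <- function(stack, labels, lifetime = NULL, theta = 0.5) {
  stopifnot(inherits(stack, "cell_stack"))
  if (!identical(dim(labels), dim(stack$AxAm))) {
    abort("label image shape does not match the stack.",
          class = "osmofret_shape_error")
  }
  lifetime <- lifetime %||% stack$lifetime
  ids <- sort(unique(labels[labels > 0L]))
  purrr::map_dfr(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    # work in the cell's bounding box for speed
    r0 <- min(px[, 1]); r1 <- max(px[, 1])
    c0 <- min(px[, 2]); c1 <- max(px[, 2])
    cellm <- labels[r0:r1, c0:c1] == id
    ax <- stack$AxAm[r0:r1, c0:c1]
    cell_area <- sum(cellm)
    med <- median(ax[cellm])

    dark <- cellm & ax < theta * med
    vac <- matrix(FALSE, nrow(cellm), ncol(cellm))
    if (any(dark)) {
      comp <- EBImage::bwlabel(EBImage::Image(dark))
      comp <- matrix(as.integer(EBImage::imageData(comp)),
                     nrow(dark), ncol(dark))
      boundary <- cellm & !erode_mask(cellm)
      touching <- unique(comp[boundary & comp > 0L])
      sizes <- tabulate(comp[comp > 0L])
      if (length(sizes) > 0) sizes[touching] <- 0L
      if (length(sizes) > 0 && max(sizes) > 0L) {
        vac <- comp == which.max(sizes)
      }
    }
    vacuole_area <- sum(vac)
    cyto <- cellm & !vac
    rr <- stack$DxAm[r0:r1, c0:c1][cyto]
    dd <- stack$DxDm[r0:r1, c0:c1][cyto]
    ratio_px <- rr[dd > 0] / dd[dd > 0]
    life_px <- if (is.null(lifetime)) NA_real_ else lifetime[r0:r1, c0:c1][cyto]
    tibble(
      cell_id = id,
      cell_area = cell_area,
      vacuole_area = vacuole_area,
      vacuolar_ratio = vacuole_area / cell_area,
      mean_lifetime = if (all(is.na(life_px))) NA_real_ else mean(life_px, na.rm = TRUE),
      mean_ratio = if (length(ratio_px)) mean(ratio_px) else NA_real_
    )
  })
}

# 4-neighbour binary erosion (edge pixels erode).
erode_mask <- function(m) {
  n <- nrow(m); p <- ncol(m)
  pad <- matrix(FALSE, n + 2L, p + 2L)
  pad[2:(n + 1L), 2:(p + 1L)] <- m
  pad[2:(n + 1L), 2:(p + 1L)] &
    pad[1:n, 2:(p + 1L)] & pad[3:(n + 2L), 2:(p + 1L)] &
    pad[2:(n + 1L), 1:p] & pad[2:(n + 1L), 3:(p + 2L)]
}

#' Pearson correlation with a closed-form t-test
#'
#' Sample Pearson correlation between two columns with the exact two-sided
#' p-value from `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param data Data frame.
#' @param x,y Column names (tidy-eval).
#'
#' @return A one-row tibble of class `correlation_result`: `r`, `p_value`,
#'   `n`, `variable_x`, `variable_y`.
#' @export
pearson_correlate <- function(data, x, y) {
  data <- as_tibble(data)
  x <- rlang::as_name(rlang::ensym(x))
  y <- rlang::as_name(rlang::ensym(y))
  assert_columns(data, c(x, y), "`data`")
  keep <- complete.cases(data[[x]], data[[y]])
  vx <- data[[x]][keep]; vy <- data[[y]][keep]
  if (length(vx) < 3L) {
    abort("at least 3 complete observations are required.",
          class = "osmofret_degenerate_input")
  }
  if (sd(vx) == 0 || sd(vy) == 0) {
    abort("zero variance in one of the variables.",
          class = "osmofret_degenerate_input")
  }
  ct <- cor.test(vx, vy, method = "pearson", alternative = "two.sided")
  structure(
    tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(vx),
           variable_x = x, variable_y = y),
    class = c("correlation_result", class(tibble())))
}

#' Per-cell ROI-based ratio analysis
#'
#' The ROI workflow for adherent mammalian cells: each cell carries one
#' background ROI (off-cell) and several cytoplasm ROIs (circles). The
#' background ROI's per-channel mean is subtracted from that cell's
#' cytoplasm ROI means, donor bleedthrough is removed
#' (`DxAm - beta * DxDm`), and the per-cell value is the mean of its
#' cytoplasm ROI ratios.
#'
#' @param stack A [cell_stack()].
#' @param rois Data frame with columns `cell_id`, `roi_id`, `role`
#'   (`"background"` or `"cytoplasm"`), `x`, `y`, `radius` (circle, px).
#' @param beta Donor bleedthrough coefficient to remove (default 0), or a
#'   [bleedthrough_correct()] result whose `beta` is used.
#'
#' @return A tibble with one row per cell: `cell_id`, `mean_ratio`,
#'   `n_rois`; per-ROI detail is attached as attribute `"rois"`.
#' @export
roi_ratio_analysis <- function(stack, rois, beta = 0) {
  stopifnot(inherits(stack, "cell_stack"))
  rois <- as_tibble(rois)
  assert_columns(rois, c("cell_id", "roi_id", "role", "x", "y", "radius"),
                 "`rois`")
  if (inherits(beta, "bleedthrough_result")) beta <- beta$beta
  assert_scalar_number(beta, "beta", lower = 0)

  h <- nrow(stack$DxDm); w <- ncol(stack$DxDm)
  roi_means <- purrr::pmap_dfr(rois, function(cell_id, roi_id, role, x, y, radius, ...) {
    cols <- max(1L, floor(x - radius)):min(w, ceiling(x + radius))
    rows <- max(1L, floor(y - radius)):min(h, ceiling(y + radius))
    inside <- outer(rows, cols, function(r, c) (c - x)^2 + (r - y)^2 <= radius^2)
    tibble(cell_id = cell_id, roi_id = roi_id, role = role,
           DxDm = mean(stack$DxDm[rows, cols][inside]),
           DxAm = mean(stack$DxAm[rows, cols][inside]),
           AxAm = mean(stack$AxAm[rows, cols][inside]))
  })

  # warn (not error) on background ROIs overlapping cytoplasm ROIs
  bg <- dplyr::filter(rois, .data$role == "background")
  cyto <- dplyr::filter(rois, .data$role == "cytoplasm")
  if (nrow(bg) > 0 && nrow(cyto) > 0) {
    overlap <- any(vapply(seq_len(nrow(bg)), function(i) {
      any((cyto$x - bg$x[i])^2 + (cyto$y - bg$y[i])^2 <
            (cyto$radius + bg$radius[i])^2)
    }, logical(1)))
    if (overlap) warn("a background ROI overlaps a cytoplasm ROI.")
  }

  bg_means <- roi_means |>
    dplyr::filter(.data$role == "background") |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(bg_DxDm = mean(.data$DxDm), bg_DxAm = mean(.data$DxAm),
                     .groups = "drop")
  detail <- roi_means |>
    dplyr::filter(.data$role == "cytoplasm") |>
    dplyr::left_join(bg_means, by = "cell_id") |>
    dplyr::mutate(
      bg_DxDm = dplyr::coalesce(.data$bg_DxDm, 0),
      bg_DxAm = dplyr::coalesce(.data$bg_DxAm, 0),
      DxDm_corr = .data$DxDm - .data$bg_DxDm,
      DxAm_corr = pmax(.data$DxAm - .data$bg_DxAm - beta * .data$DxDm_corr, 0),
      ratio = .data$DxAm_corr / .data$DxDm_corr
    )
  out <- detail |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio), n_rois = dplyr::n(),
                     .groups = "drop")
  attr(out, "rois") <- detail
  out
}
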