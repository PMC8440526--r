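#' Construct a multi-channel cell image stack
#'
#' Container for registered DxDm / DxAm / AxAm intensity images of a field
#' of cells, with an optional lifetime image (ns). Channels may be 2-D
#' matrices or 3-D arrays (rows x cols x z-planes); all shapes must agree.
#' Pixel convention is row-major with the origin at the top-left; areas are
#' reported in px^2, with `pixel_size` (um/px) available for conversion.
#'
#' @param DxDm,DxAm,AxAm Intensity images (matrix or 3-D array, au).
#' @param lifetime Optional lifetime image in ns (`NA` outside cells).
#' @param pixel_size Pixel size in micrometres per pixel.
#'
#' @return A `cell_stack` object.
#' @export
cell_stack <- function(DxDm, DxAm, AxAm, lifetime = NULL, pixel_size = 0.24) {
  dims <- dim(DxDm)
  if (is.null(dims) || !length(dims) %in% c(2L, 3L)) {
    abort("channels must be matrices or 3-D arrays.",
          class = "osmofret_invalid_parameter")
  }
  for (ch in list(DxAm, AxAm)) {
    if (!identical(dim(ch), dims)) {
      abort("all channels must share the same dimensions.",
            class = "osmofret_shape_error")
    }
  }
  if (!is.null(lifetime) && !identical(dim(lifetime)[1:2], dims[1:2])) {
    abort("lifetime image must match the channel x/y shape.",
          class = "osmofret_shape_error")
  }
  structure(
    list(DxDm = DxDm, DxAm = DxAm, AxAm = AxAm, lifetime = lifetime,
         pixel_size = pixel_size,
         z_planes = if (length(dims) == 3L) dims[3] else 1L),
    class = "cell_stack"
  )
}

#' @export
print.cell_stack <- function(x, ...) {
  d <- dim(x$DxDm)
  cat(sprintf("<cell_stack> %d x %d px, %d z-plane(s), %s lifetime image, %.3g um/px\n",
              d[1], d[2], x$z_planes,
              if (is.null(x$lifetime)) "no" else "with", x$pixel_size))
  invisible(x)
}

channel_names <- function() c("DxDm", "DxAm", "AxAm")
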