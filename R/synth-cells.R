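#' Ground truth for a synthetic cell population with vacuoles
#'
#' Parameters of a simulated field of disk-shaped yeast-like cells, each
#' carrying a dark disk vacuole (the sensor is excluded from the vacuole).
#' Per-cell baseline donor lifetime follows
#' `intercept + baseline_lifetime_slope * VR + noise` and the fractional
#' lifetime change after hyperosmotic shock follows the buffering model
#' `delta = -(shock_delta_mean - buffering_slope * VR) + noise`, where `VR`
#' is the vacuolar ratio (vacuole area / cell area). With the defaults the
#' planted correlations are +0.44 between vacuolar ratio and baseline
#' lifetime and -0.47 between vacuolar ratio and delta-lifetime, mirroring
#' the single-cell heterogeneity structure the pipeline is designed to
#' recover (large vacuoles: longer baseline lifetime, larger lifetime drop).
#'
#' @param n_cells Number of cells to place.
#' @param cell_radius_range Min/max cell radius in pixels.
#' @param vacuolar_ratio_range Min/max vacuolar ratio, within `[0, 1)`.
#' @param tau_donor_only Unquenched donor lifetime in ns.
#' @param baseline_lifetime_intercept Baseline lifetime at VR = 0, ns.
#' @param baseline_lifetime_slope ns of baseline lifetime per unit VR.
#' @param shock_delta_mean Mean fractional lifetime drop at VR = 0.
#' @param buffering_slope Change of the (signed) delta-lifetime per unit VR;
#'   negative values make large-vacuole cells drop more.
#' @param noise_sd_lifetime Cell-to-cell lifetime noise SD, ns.
#' @param noise_sd_delta Cell-to-cell delta-lifetime noise SD (fraction).
#' @param image_shape Image height/width in pixels.
#' @param seed Integer seed; all randomness of [gen_cell_population()] flows
#'   from it.
#'
#' @return A `population_truth` list.
#' @export
population_truth <- function(n_cells = 100, cell_radius_range = c(12, 18),
                             vacuolar_ratio_range = c(0.05, 0.45),
                             tau_donor_only = 3.62,
                             baseline_lifetime_intercept = 2.85,
                             baseline_lifetime_slope = 0.8,
                             shock_delta_mean = 0.20,
                             buffering_slope = -0.23,
                             noise_sd_lifetime = 0.19,
                             noise_sd_delta = 0.05,
                             image_shape = c(512, 512), seed = 1L) {
  assert_count(n_cells, "n_cells", lower = 0L)
  if (vacuolar_ratio_range[1] < 0 || vacuolar_ratio_range[2] >= 1 ||
      diff(vacuolar_ratio_range) < 0) {
    abort("`vacuolar_ratio_range` must lie within [0, 1).",
          class = "osmofret_invalid_parameter")
  }
  assert_scalar_number(tau_donor_only, "tau_donor_only", lower = 0, strict_lower = TRUE)
  structure(
    list(n_cells = as.integer(n_cells), cell_radius_range = cell_radius_range,
         vacuolar_ratio_range = vacuolar_ratio_range,
         tau_donor_only = tau_donor_only,
         baseline_lifetime_intercept = baseline_lifetime_intercept,
         baseline_lifetime_slope = baseline_lifetime_slope,
         shock_delta_mean = shock_delta_mean, buffering_slope = buffering_slope,
         noise_sd_lifetime = noise_sd_lifetime, noise_sd_delta = noise_sd_delta,
         image_shape = as.integer(image_shape), seed = as.integer(seed)),
    class = "population_truth"
  )
}

#' Simulate pre- and post-shock image stacks of a cell population
#'
#' Places non-overlapping disk cells with strictly interior disk vacuoles,
#' draws per-cell lifetimes and shock responses from the planted models, and
#' renders DxDm/DxAm/AxAm intensity images plus a lifetime image for both
#' the baseline and the post-shock state. Channel intensities follow the
#' lifetime through `E = 1 - tau / tau_donor_only`, with the donor-excitation
#' budget split so that the pixel ratio `DxAm/DxDm = E/(1-E)` is monotone in
#' `E`. The ground-truth table is returned for recovery tests.
#'
#' @param truth A [population_truth()] object.
#' @param max_place_tries Bounded retries for non-overlapping placement.
#'
#' @return A list of class `cell_population` with elements `pre` and `post`
#'   ([cell_stack()] objects with lifetime images) and `truth`, a tibble of
#'   per-cell ground truth (position, radius, areas, vacuolar ratio,
#'   lifetimes, delta-lifetime).
#' @export
gen_cell_population <- function(truth, max_place_tries = 200L * max(1L, truth$n_cells)) {
  stopifnot(inherits(truth, "population_truth"))
  h <- truth$image_shape[1]
  w <- truth$image_shape[2]

  if (truth$n_cells == 0L) {
    z <- matrix(0, h, w)
    empty <- cell_stack(DxDm = z, DxAm = z, AxAm = z, lifetime = z)
    return(structure(list(pre = empty, post = empty,
                          truth = empty_cell_truth()),
                     class = "cell_population"))
  }

  with_local_seed(truth$seed, {
    geom <- place_cells(truth, h, w, max_place_tries)
    n <- nrow(geom)

    vr <- geom$vacuolar_ratio_true
    tau_base <- truth$baseline_lifetime_intercept +
      truth$baseline_lifetime_slope * vr +
      rnorm(n, sd = truth$noise_sd_lifetime)
    tau_base <- pmax(tau_base, 0.2)
    delta <- -(truth$shock_delta_mean - truth$buffering_slope * vr) +
      rnorm(n, sd = truth$noise_sd_delta)
    tau_post <- pmax(tau_base * (1 + delta), 0.2)

    cells <- dplyr::mutate(geom,
      cell_id = seq_len(n),
      tau_baseline_true = tau_base,
      delta_lifetime_true = delta,
      tau_post_true = tau_post,
      e_baseline_true = 1 - tau_base / truth$tau_donor_only
    )

    pre <- render_population(cells, tau_base, truth, h, w)
    post <- render_population(cells, tau_post, truth, h, w)

    structure(list(pre = pre, post = post, truth = as_tibble(cells)),
              class = "cell_population")
  })
}

empty_cell_truth <- function() {
  tibble(x = numeric(0), y = numeric(0), radius = numeric(0),
         vacuole_x = numeric(0), vacuole_y = numeric(0),
         vacuole_radius = numeric(0), cell_area_true = numeric(0),
         vacuole_area_true = numeric(0), vacuolar_ratio_true = numeric(0),
         cell_id = integer(0), tau_baseline_true = numeric(0),
         delta_lifetime_true = numeric(0), tau_post_true = numeric(0),
         e_baseline_true = numeric(0))
}

# Rejection-sample non-overlapping cell centers; vacuole strictly interior.
place_cells <- function(truth, h, w, max_tries) {
  n <- truth$n_cells
  rr <- truth$cell_radius_range
  vrr <- truth$vacuolar_ratio_range
  xs <- ys <- rs <- numeric(0)
  tries <- 0L
  margin <- 2
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf("could not place %d non-overlapping cells in a %dx%d image after %d tries.",
                    n, h, w, max_tries),
            class = "osmofret_placement_error")
    }
    r <- runif(1, rr[1], rr[2])
    x <- runif(1, r + margin, w - r - margin)
    y <- runif(1, r + margin, h - r - margin)
    if (all((xs - x)^2 + (ys - y)^2 > (rs + r + margin)^2)) {
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
    }
  }
  vr <- runif(n, vrr[1], vrr[2])
  vrad <- sqrt(vr) * rs
  # vacuole center offset keeps the vacuole >= 2 px inside the cell edge
  max_off <- pmax(rs - vrad - 2, 0)
  off <- runif(n, 0, max_off)
  ang <- runif(n, 0, 2 * pi)
  tibble(
    x = xs, y = ys, radius = rs,
    vacuole_x = xs + off * cos(ang), vacuole_y = ys + off * sin(ang),
    vacuole_radius = vrad,
    cell_area_true = pi * rs^2, vacuole_area_true = pi * vrad^2,
    vacuolar_ratio_true = vr
  )
}

# Render one state (baseline or post-shock) of the population into images.
render_population <- function(cells, tau, truth, h, w) {
  i0 <- 200          # donor-excitation intensity budget per cytoplasm pixel
  axam_cyto <- 120   # direct acceptor-excitation signal in the cytoplasm
  dark <- 6          # residual intensity inside vacuoles (sensor excluded)
  bg_level <- 4

  e <- pmax(1 - tau / truth$tau_donor_only, 0.02)  # floor for rendering only
  dxdm <- matrix(0, h, w); dxam <- matrix(0, h, w)
  axam <- matrix(0, h, w); life <- matrix(NA_real_, h, w)

  xg <- matrix(rep(seq_len(w), each = h), h, w)
  yg <- matrix(rep(seq_len(h), times = w), h, w)
  for (i in seq_len(nrow(cells))) {
    cm <- (xg - cells$x[i])^2 + (yg - cells$y[i])^2 <= cells$radius[i]^2
    vm <- (xg - cells$vacuole_x[i])^2 + (yg - cells$vacuole_y[i])^2 <=
      cells$vacuole_radius[i]^2
    cyto <- cm & !vm
    dxdm[cyto] <- i0 * (1 - e[i])
    dxam[cyto] <- i0 * e[i]
    axam[cyto] <- axam_cyto
    dxdm[vm] <- dark; dxam[vm] <- dark; axam[vm] <- dark
    life[cyto] <- tau[i] + rnorm(sum(cyto), sd = 0.02)
  }
  noise <- function(m) pmax(m * exp(rnorm(length(m), sd = 0.05)) +
                              rnorm(length(m), mean = bg_level, sd = 1), 0)
  cell_stack(
    DxDm = matrix(noise(dxdm), h, w),
    DxAm = matrix(noise(dxam), h, w),
    AxAm = matrix(noise(axam), h, w),
    lifetime = life
  )
}
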