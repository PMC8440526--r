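test_that("preprocessing sums z-planes and subtracts planted backgrounds", {
  plane <- matrix(10, 8, 8)
  arr <- array(rep(plane, 3), dim = c(8, 8, 3))
  st <- cell_stack(DxDm = arr, DxAm = arr, AxAm = arr)
  out <- preprocess_stack(st, background = NULL)
  expect_true(all(out$DxDm == 30))
  # identity on a single plane with zero background
  st1 <- cell_stack(matrix(5, 4, 4), matrix(5, 4, 4), matrix(5, 4, 4))
  expect_equal(preprocess_stack(st1, background = NULL)$DxAm, matrix(5, 4, 4))
  # ROI background subtraction removes a planted uniform offset exactly
  base <- disk_stack()
  shifted <- cell_stack(base$DxDm + 50, base$DxAm + 50, base$AxAm + 50)
  roi <- list(x0 = 1, y0 = 1, x1 = 5, y1 = 5)  # off-cell corner
  out2 <- preprocess_stack(shifted, background = roi)
  expect_equal(out2$DxDm, base$DxDm)
  expect_error(preprocess_stack(base, background = list(x0 = 0, y0 = 1,
                                                        x1 = 99, y1 = 5)),
               class = "osmofret_bounds_error")
})

test_that("cytoplasm means on synthetic cells survive background subtraction", {
  pop <- gen_cell_population(population_truth(n_cells = 8,
                                              image_shape = c(220, 220),
                                              seed = 13))
  pre <- preprocess_stack(pop$pre, background = 5)
  tr <- pop$truth
  h <- nrow(pre$DxDm)
  xg <- matrix(rep(seq_len(h), each = h), h, h)
  yg <- matrix(rep(seq_len(h), times = h), h, h)
  i0 <- 200
  for (i in seq_len(3)) {
    cyto <- (xg - tr$x[i])^2 + (yg - tr$y[i])^2 <= (tr$radius[i] - 1)^2 &
      (xg - tr$vacuole_x[i])^2 + (yg - tr$vacuole_y[i])^2 > (tr$vacuole_radius[i] + 1)^2
    planted <- i0 * (1 - max(tr$e_baseline_true[i], 0.02))
    expect_lt(abs(mean(pre$DxDm[cyto]) - planted) / planted, 0.05)
  }
})

test_that("ratiometric recipe handles the trivial masks exactly", {
  st <- disk_stack(ratio = 1)
  ri <- ratiometric_image(st, mask_threshold = 50)
  expect_true(all(ri$ratio[ri$mask == 1] == 1))
  expect_true(all(ri$ratio[ri$mask == 0] == 0))
  # unreachable threshold -> empty mask -> all-zero ratio image
  ri0 <- ratiometric_image(st, mask_threshold = 1e9)
  expect_true(all(ri0$ratio == 0))
  expect_true(all(ri0$mask == 0))
})

test_that("ratiometric recipe matches the naive oracle pixel-for-pixel", {
  set.seed(99)
  for (rep in 1:3) {
    st <- cell_stack(matrix(runif(64^2, 0, 200), 64, 64),
                     matrix(runif(64^2, 0, 200), 64, 64),
                     matrix(runif(64^2, 0, 255), 64, 64))
    thr <- 120
    mine <- ratiometric_image(st, blur_sigma = 1, mask_threshold = thr)
    ref <- naive_ratiometric(st, sigma = 1, threshold = thr)
    expect_equal(mine$mask, ref$mask)
    expect_equal(mine$ratio, ref$ratio, tolerance = 1e-12)
  }
})

test_that("ratiometric recipe is invariant to joint channel rescaling", {
  st <- disk_stack(ratio = 1.4)
  r1 <- ratiometric_image(st, mask_threshold = 50)
  st2 <- cell_stack(st$DxDm * 3, st$DxAm * 3, st$AxAm * 3)
  r2 <- ratiometric_image(st2, mask_threshold = 150)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("segmentation counts disjoint disks and handles blank images", {
  two <- cell_stack(matrix(0, 80, 80), matrix(0, 80, 80), {
    m <- matrix(0, 80, 80)
    xg <- matrix(rep(1:80, each = 80), 80, 80)
    yg <- matrix(rep(1:80, times = 80), 80, 80)
    m[(xg - 22)^2 + (yg - 25)^2 <= 100] <- 100
    m[(xg - 58)^2 + (yg - 55)^2 <= 121] <- 100
    m
  })
  lab <- segment_cells(two)
  expect_equal(max(lab), 2)
  blank <- cell_stack(matrix(0, 40, 40), matrix(0, 40, 40), matrix(0, 40, 40))
  expect_equal(max(segment_cells(blank)), 0)
})

test_that("segmentation recovers a generated field with high overlap", {
  pop <- gen_cell_population(population_truth(n_cells = 30,
                                              image_shape = c(340, 340),
                                              seed = 33))
  lab <- segment_cells(pop$pre)
  expect_equal(max(lab), 30)
  tr <- pop$truth
  h <- nrow(pop$pre$AxAm)
  xg <- matrix(rep(seq_len(h), each = h), h, h)
  yg <- matrix(rep(seq_len(h), times = h), h, h)
  ious <- vapply(seq_len(30), function(i) {
    truth_mask <- (xg - tr$x[i])^2 + (yg - tr$y[i])^2 <= tr$radius[i]^2
    ids <- lab[truth_mask]
    id <- as.integer(names(which.max(table(ids[ids > 0]))))
    seg_mask <- lab == id
    sum(seg_mask & truth_mask) / sum(seg_mask | truth_mask)
  }, 0)
  expect_true(all(ious >= 0.9))
})

test_that("vacuolar ratio of a centred dark disk is its area fraction", {
  n <- 64
  xg <- matrix(rep(1:n, each = n), n, n)
  yg <- matrix(rep(1:n, times = n), n, n)
  cell <- (xg - 32)^2 + (yg - 32)^2 <= 20^2
  vac <- (xg - 32)^2 + (yg - 32)^2 <= 10^2
  ax <- matrix(0, n, n); ax[cell] <- 100; ax[vac] <- 5
  st <- cell_stack(ax, ax, ax)
  labels <- matrix(0L, n, n); labels[cell] <- 1L
  rec <- vacuolar_ratio_stats(st, labels)
  expect_equal(rec$vacuolar_ratio, 0.25, tolerance = 0.02)
  # no sub-threshold region -> ratio 0
  ax2 <- matrix(0, n, n); ax2[cell] <- 100
  rec2 <- vacuolar_ratio_stats(cell_stack(ax2, ax2, ax2), labels)
  expect_equal(rec2$vacuolar_ratio, 0)
  expect_error(vacuolar_ratio_stats(st, labels[1:10, 1:10]),
               class = "osmofret_shape_error")
})

test_that("per-cell vacuolar ratios recover the planted values", {
  pop <- gen_cell_population(population_truth(n_cells = 40,
                                              image_shape = c(400, 400),
                                              seed = 44))
  lab <- segment_cells(pop$pre)
  st <- vacuolar_ratio_stats(pop$pre, lab)
  tr <- pop$truth
  cent <- vapply(sort(unique(lab[lab > 0])), function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    c(mean(px[, 2]), mean(px[, 1]))
  }, c(0, 0))
  idx <- apply(cent, 2, function(p) which.min((tr$x - p[1])^2 + (tr$y - p[2])^2))
  err <- abs(st$vacuolar_ratio - tr$vacuolar_ratio_true[idx])
  expect_gte(mean(err <= 0.03), 0.95)
  expect_true(all(st$vacuolar_ratio >= 0 & st$vacuolar_ratio <= 1))
  expect_true(all(st$vacuole_area <= st$cell_area))
})

test_that("pearson_correlate matches the closed-form t-test", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  r <- pearson_correlate(d, x, y)
  expect_equal(r$r, 1)
  expect_lt(r$p_value, 1e-12)
  # orthogonalized y gives r = 0 and the exact t-distribution p-value
  set.seed(7)
  x <- rnorm(20); y <- rnorm(20)
  y <- y - mean(y); x0 <- x - mean(x)
  y <- y - sum(y * x0) / sum(x0^2) * x0
  r0 <- pearson_correlate(tibble::tibble(x = x, y = y), x, y)
  expect_equal(r0$r, 0, tolerance = 1e-12)
  # p equals the closed form for a generic case
  set.seed(8)
  d2 <- tibble::tibble(x = rnorm(30), y = rnorm(30))
  rr <- pearson_correlate(d2, x, y)
  tt <- rr$r * sqrt((rr$n - 2) / (1 - rr$r^2))
  expect_equal(rr$p_value, 2 * pt(-abs(tt), rr$n - 2))
  expect_error(pearson_correlate(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               class = "osmofret_degenerate_input")
  expect_error(pearson_correlate(tibble::tibble(x = 1:2, y = 2:3), x, y),
               class = "osmofret_degenerate_input")
})

test_that("planted bivariate correlation is recovered in distribution", {
  rs <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    x <- rnorm(100)
    y <- 0.44 * x + sqrt(1 - 0.44^2) * rnorm(100)
    pearson_correlate(tibble::tibble(x = x, y = y), x, y)$r
  }, 0)
  expect_lt(abs(median(rs) - 0.44), 0.05)
})

test_that("ROI analysis subtracts backgrounds exactly and ranks planted gradients", {
  st <- disk_stack(n = 96, cx = 60, cy = 60, r = 25, ratio = 1.0)
  rois <- tibble::tibble(
    cell_id = 1, roi_id = 1:5,
    role = c("background", rep("cytoplasm", 4)),
    x = c(12, 55, 65, 60, 60), y = c(12, 60, 60, 55, 65), radius = 4)
  out <- roi_ratio_analysis(st, rois)
  expect_equal(out$mean_ratio, 1)
  expect_equal(out$n_rois, 4)
  # planted uniform background on all channels cancels exactly
  st2 <- cell_stack(st$DxDm + 100, st$DxAm + 100, st$AxAm + 100)
  out2 <- roi_ratio_analysis(st2, rois)
  expect_equal(out2$mean_ratio, out$mean_ratio, tolerance = 1e-12)
  # overlapping background ROI warns but still computes
  rois_bad <- rois; rois_bad$x[1] <- 55; rois_bad$y[1] <- 60
  expect_warning(roi_ratio_analysis(st, rois_bad))
})

test_that("per-cell ROI ratios rank with a planted efficiency gradient", {
  n <- 150
  es <- seq(0.05, 0.45, length.out = 5)
  dx <- matrix(0, n, n); da <- matrix(0, n, n); ax <- matrix(0, n, n)
  centers <- cbind(x = seq(20, 130, length.out = 5), y = 75)
  xg <- matrix(rep(1:n, each = n), n, n)
  yg <- matrix(rep(1:n, times = n), n, n)
  for (i in 1:5) {
    inside <- (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2 <= 81
    dx[inside] <- 100 * (1 - es[i])
    da[inside] <- 100 * es[i]
    ax[inside] <- 80
  }
  st <- cell_stack(dx, da, ax)
  rois <- purrr::map_dfr(1:5, function(i) tibble::tibble(
    cell_id = i, roi_id = 1:5,
    role = c("background", rep("cytoplasm", 4)),
    x = c(centers[i, 1], centers[i, 1] + c(-3, 3, 0, 0)),
    y = c(8, centers[i, 2] + c(0, 0, -3, 3)), radius = 2.5))
  out <- roi_ratio_analysis(st, rois)
  expect_equal(cor(out$mean_ratio, es, method = "spearman"), 1)
})
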