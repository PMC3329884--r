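test_that("gradient matches the central-difference definition", {
  const <- volume_image(array(7, c(5, 5, 5)))
  g <- compute_gradient(const)
  expect_all_near(g$gx, array(0, c(5, 5, 5)))
  expect_all_near(g$gy, 0); expect_all_near(g$gz, 0)

  ramp <- volume_image(array(rep(2 * (1:6), times = 36), c(6, 6, 6)))
  g <- compute_gradient(ramp)
  expect_all_near(g$gx[2:5, , ], 2)
  expect_all_near(g$gy, 0)
  expect_all_near(g$gz, 0)
  # clamped edges: one-sided difference halved
  expect_all_near(g$gx[1, , ], 1)

  set.seed(5)
  a <- array(rnorm(125), c(5, 5, 5))
  g <- compute_gradient(volume_image(a))
  ref <- naive_gradient(a)
  expect_all_near(g$gx, ref$gx, 1e-12)
  expect_all_near(g$gy, ref$gy, 1e-12)
  expect_all_near(g$gz, ref$gz, 1e-12)
})

test_that("2D gradient has zero z-component; degenerate axes error", {
  img <- volume_image(matrix(rnorm(100), 10, 10))
  g <- compute_gradient(img)
  expect_all_near(g$gz, 0)
  expect_error(compute_gradient(volume_image(array(0, c(2, 5, 5)))),
               "at least 3")
})

test_that("detection finds points only where gradient energy lives", {
  a <- array(0, c(16, 16, 16))
  a[8:10, 8:10, 8:10] <- 100
  img <- volume_image(a)
  cfg <- detection_config(intensity_window = c(-Inf, Inf), min_saliency = 1,
                          nms_radius = 0, max_points = 1e5)
  pts <- detect_feature_points(img, cfg)
  expect_gt(nrow(pts), 0)
  # all detected points lie within 2 voxels of the cube (gradient support)
  expect_true(all(pts$i >= 6 & pts$i <= 12 & pts$j >= 6 & pts$j <= 12 &
                  pts$k >= 6 & pts$k <= 12))
  # saliency equals the exhaustive 3x3x3 gradient-energy sum
  ref <- naive_gradient(a)
  e <- ref$gx^2 + ref$gy^2 + ref$gz^2
  cl <- function(v) min(max(v, 1L), 16L)
  for (r in sample(nrow(pts), min(5, nrow(pts)))) {
    s <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
      s <- s + e[cl(pts$i[r] + dx), cl(pts$j[r] + dy), cl(pts$k[r] + dz)]
    expect_equal(pts$saliency[r], s, tolerance = 1e-12)
  }
})

test_that("constant images and exclusive windows detect nothing", {
  const <- volume_image(array(5, c(12, 12, 12)))
  expect_warning(pts <- detect_feature_points(const), "no feature points")
  expect_equal(nrow(pts), 0L)

  a <- array(0, c(16, 16, 16)); a[8:10, 8:10, 8:10] <- 100
  cfg <- detection_config(intensity_window = c(200, 300), min_saliency = 1)
  expect_warning(pts <- detect_feature_points(volume_image(a), cfg))
  expect_equal(nrow(pts), 0L)
})

test_that("detection is deterministic, monotone in threshold, window-safe", {
  ph <- small_phantom_2d(seed = 11)
  p1 <- detect_feature_points(ph$image)
  p2 <- detect_feature_points(ph$image)
  expect_identical(p1, p2)

  lo <- detect_feature_points(ph$image,
          detection_config(min_saliency = 50, nms_radius = 0))
  hi <- detect_feature_points(ph$image,
          detection_config(min_saliency = 500, nms_radius = 0))
  expect_lte(nrow(hi), nrow(lo))
  expect_true(all(paste(hi$i, hi$j) %in% paste(lo$i, lo$j)))

  # every point admits a full descriptor window
  d <- ph$image$dims
  expect_true(all(p1$i >= 5 & p1$i <= d[1] - 4 & p1$j >= 5 & p1$j <= d[2] - 4))
  # non-maximum suppression: retained points are spread by nms_radius
  if (nrow(p1) > 1) {
    xy <- cbind(p1$x, p1$y)
    expect_gt(min(stats::dist(xy)), 3)
  }
})

test_that("detection_config rejects invalid settings", {
  expect_error(detection_config(intensity_window = c(5, 1)), "low <= high")
  expect_error(detection_config(border_margin = 2), ">= 4")
  expect_error(detection_config(max_points = 0), ">= 1")
  expect_error(detection_config(nms_radius = -1), ">= 0")
})
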