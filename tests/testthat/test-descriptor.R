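test_that("constant image gives the all-zero descriptor", {
  img <- volume_image(array(3, c(12, 12, 12)))
  d <- compute_descriptor(img, c(6, 6, 6))
  expect_length(d, 192)
  expect_true(all(d == 0))
})

test_that("pure x-ramp puts all mass in the 0-degree bins of xy and zx", {
  img <- volume_image(array(rep(2 * (1:12), times = 144), c(12, 12, 12)))
  d <- compute_descriptor(img, c(6, 6, 6))
  m <- matrix(d, nrow = 8, byrow = TRUE)   # quadrant x (plane,bin)
  for (q in 1:8) {
    nz <- which(m[q, ] > 0)
    # component 1 = xy plane bin 0; component 17 = zx plane bin 0
    expect_identical(nz, c(1L, 17L))
    # 64 voxels per quadrant, in-plane magnitude 2 each
    expect_equal(unname(m[q, nz]), c(128, 128))
  }
})

test_that("descriptors equal the naive triple-loop reference", {
  set.seed(6)
  img <- volume_image(array(rnorm(12^3, sd = 50), c(12, 12, 12)))
  for (centre in list(c(5, 5, 5), c(6, 7, 8), c(8, 5, 6))) {
    d <- compute_descriptor(img, centre)
    expect_all_near(d, naive_descriptor(img, centre), 1e-9)
  }
  img2 <- volume_image(matrix(rnorm(18^2, sd = 50), 18, 18))
  d2 <- compute_descriptor(img2, c(9, 9, 1))
  expect_length(d2, 32)
  expect_all_near(d2, naive_descriptor(img2, c(9, 9, 1), mode2d = TRUE), 1e-9)
})

test_that("descriptors are shift-invariant and scale linearly in intensity", {
  set.seed(7)
  a <- array(rnorm(12^3, sd = 20), c(12, 12, 12))
  base <- compute_descriptor(volume_image(a), c(6, 6, 6))
  shifted <- compute_descriptor(volume_image(a + 135), c(6, 6, 6))
  expect_all_near(base, shifted, 1e-9)
  scaled <- compute_descriptor(volume_image(3 * a), c(6, 6, 6))
  expect_all_near(scaled, 3 * base, 1e-9)
})

test_that("per-plane histogram mass conserves in-plane gradient magnitude", {
  set.seed(8)
  img <- volume_image(array(rnorm(14^3, sd = 30), c(14, 14, 14)))
  centre <- c(7, 7, 7)
  d <- compute_descriptor(img, centre)
  g <- compute_gradient(img)
  win <- list(centre[1] + (-4:3), centre[2] + (-4:3), centre[3] + (-4:3))
  planes <- list(c("gx", "gy"), c("gy", "gz"), c("gx", "gz"))
  m <- matrix(d, nrow = 8, byrow = TRUE)
  for (p in 1:3) {
    mass <- sum(m[, (p - 1) * 8 + 1:8])
    inplane <- sqrt(g[[planes[[p]][1]]][win[[1]], win[[2]], win[[3]]]^2 +
                    g[[planes[[p]][2]]][win[[1]], win[[2]], win[[3]]]^2)
    expect_equal(mass, sum(inplane), tolerance = 1e-9)
  }
})

test_that("windows that leave the image are rejected with the point named", {
  img <- volume_image(array(rnorm(12^3), c(12, 12, 12)))
  expect_error(compute_descriptor(img, c(4, 6, 6)), "point 1 at \\(4, 6, 6\\)")
  expect_error(compute_descriptor(img, c(6, 6, 10)), "out of bounds")
})

test_that("descriptor_distance is the componentwise squared-L2 sum", {
  expect_equal(descriptor_distance(rep(0, 192), rep(0, 192)), 0)
  b <- rep(0, 192); b[42] <- 3
  expect_equal(descriptor_distance(rep(0, 192), b), 9)
  set.seed(9)
  u <- runif(192); v <- runif(192)
  expect_equal(descriptor_distance(u, v), naive_distance(u, v),
               tolerance = 1e-12)
  expect_equal(descriptor_distance(u, v), descriptor_distance(v, u))
  d2 <- make_desc(matrix(runif(32), 1), mode = "2d")
  d3 <- make_desc(matrix(runif(192), 1), mode = "3d")
  expect_error(descriptor_distance(d2, d3), "2D and 3D")
})

test_that("count weighting and normalization behave as documented", {
  set.seed(10)
  img <- volume_image(array(rnorm(12^3, sd = 10), c(12, 12, 12)))
  pts <- data.frame(i = 6L, j = 6L, k = 6L)
  cnt <- compute_descriptors(img, pts, weighting = "count")
  expect_equal(sum(cnt), 3 * 512)   # every voxel lands in one bin per plane
  nrm <- compute_descriptors(img, pts, normalize = TRUE)
  expect_equal(sum(unclass(nrm)^2), 1, tolerance = 1e-12)
})
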