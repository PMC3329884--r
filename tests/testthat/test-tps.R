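test_that("the radial basis U(r) = r^2 log r^2 has its limit values", {
  expect_equal(kernel_U(0), 0)
  expect_equal(kernel_U(1), 0)
  expect_equal(kernel_U(2), 4 * log(4))
  expect_equal(kernel_U(2), 5.545177, tolerance = 1e-6)
  expect_error(kernel_U(-1), "non-negative")
  expect_equal(kernel_U(c(0, 3), kernel = "r"), c(0, 3))
})

test_that("identity and translation correspondences fit with zero weights", {
  set.seed(17)
  src <- matrix(runif(30, 0, 100), 10, 3)
  id <- fit_tps(src, src)
  expect_lt(max(abs(id$weights)), 1e-8)
  p <- matrix(runif(30, -50, 150), 10, 3)
  expect_all_near(evaluate_tps(id, p), p, 1e-6)

  tr <- fit_tps(src, src + rep(c(1.5, -2, 3), each = 10))
  expect_lt(max(abs(tr$weights)), 1e-8)
  expect_all_near(evaluate_tps(tr, p), p + rep(c(1.5, -2, 3), each = 10), 1e-6)
})

test_that("affine destinations are reproduced exactly with vanishing weights", {
  set.seed(18)
  src <- matrix(runif(30, 0, 100), 10, 3)
  A <- rbind(c(5, -3, 10), diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3))
  mod <- fit_tps(src, cbind(1, src) %*% A)
  expect_lt(max(abs(mod$weights)), 1e-8)
  test_pts <- matrix(runif(300, 0, 100), 100, 3)
  expect_all_near(evaluate_tps(mod, test_pts), cbind(1, test_pts) %*% A, 1e-6)
})

test_that("fitted models interpolate control points and obey side conditions", {
  set.seed(19)
  for (d in 2:3) for (n in c(d + 2, 15)) {
    src <- matrix(runif(n * d, 0, 100), n, d)
    dst <- src + matrix(rnorm(n * d, sd = 5), n, d)
    mod <- fit_tps(src, dst, dimensions = d)
    expect_all_near(evaluate_tps(mod, src), dst, 1e-6)
    expect_lt(max(abs(colSums(mod$weights))), 1e-8)
    expect_lt(max(abs(t(src) %*% mod$weights)), 1e-8)
  }
})

test_that("evaluate_tps matches the scalar reference of the warp equation", {
  set.seed(20)
  src <- matrix(runif(24, 0, 100), 8, 3)
  dst <- src + matrix(rnorm(24, sd = 8), 8, 3)
  mod <- fit_tps(src, dst)
  for (rep in 1:10) {
    pt <- runif(3, -20, 120)
    got <- evaluate_tps(mod, pt)[1, ]
    ref <- naive_tps_eval(mod, pt)
    expect_all_near(got, ref, 1e-9 * max(1, max(abs(ref))))
  }
})

test_that("degenerate control-point geometry is rejected", {
  line <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(fit_tps(line, line + 1, dimensions = 2), "collinear")
  plane <- cbind(matrix(runif(10, 0, 10), 5, 2), 0)
  expect_error(fit_tps(plane, plane, dimensions = 3), "coplanar")
  expect_error(fit_tps(matrix(runif(9), 3, 3), matrix(runif(6), 2, 3)),
               "source has 3")
  expect_error(fit_tps(matrix(runif(6), 2, 3), matrix(runif(6), 2, 3)),
               "at least 4")
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10),
               c(3, 4, 5))
  expect_warning(mod <- fit_tps(dup, dup + 2), "duplicate")
  expect_equal(nrow(mod$control_points), 5L)
})

test_that("tps_to_field stores displacement on the target grid", {
  grid <- volume_image(array(0, c(6, 7, 8)), spacing = c(2, 1, 1.5),
                       origin = c(3, -2, 0))
  set.seed(21)
  src <- matrix(runif(18, 0, 10), 6, 3)
  idm <- fit_tps(src, src)
  f0 <- tps_to_field(idm, grid)
  expect_all_near(f0$vectors, 0, 1e-6)

  trm <- fit_tps(src, src + rep(c(2, 0, -1), each = 6))
  ft <- tps_to_field(trm, grid)
  expect_all_near(ft$vectors[, , , 1], 2, 1e-6)
  expect_all_near(ft$vectors[, , , 2], 0, 1e-6)
  expect_all_near(ft$vectors[, , , 3], -1, 1e-6)

  # control points on voxel centres reproduce their displacements
  src2 <- voxel_to_physical(grid, rbind(c(2, 2, 2), c(5, 3, 6), c(3, 6, 4),
                                        c(2, 5, 7), c(4, 2, 3)))
  disp <- matrix(rnorm(15, sd = 0.5), 5, 3)
  mod2 <- fit_tps(src2, src2 + disp)
  f2 <- tps_to_field(mod2, grid)
  for (r in 1:5) {
    v <- physical_to_voxel(grid, src2[r, , drop = FALSE])
    expect_all_near(f2$vectors[v[1], v[2], v[3], ], disp[r, ], 1e-6)
  }
})

test_that("warping with zero or integer-shift fields is exact", {
  set.seed(22)
  a <- array(rnorm(10 * 11 * 12), c(10, 11, 12))
  img <- volume_image(a, spacing = c(2, 2, 2))
  zero <- displacement_field(array(0, c(10, 11, 12, 3)), spacing = c(2, 2, 2))
  expect_all_near(warp_image(img, zero)$data, a, 1e-12)

  # displacement (+2, 0, 0) mm = one voxel: out(i) = template(i+1)
  shift <- displacement_field(
    array(rep(c(2, 0, 0), each = 10 * 11 * 12), c(10, 11, 12, 3)),
    spacing = c(2, 2, 2))
  w <- warp_image(img, shift)
  expect_all_near(w$data[1:9, , ], a[2:10, , ], 1e-12)
  expect_all_near(w$data[10, , ], min(a))  # out of bounds -> fill
})

test_that("warping by a smooth field and its negation round-trips", {
  spec <- phantom_spec(dims = c(48, 48, 48), spacing = c(2, 2, 2),
                       n_blobs = 300, seed = 23)
  ph <- generate_phantom(spec)
  def <- lobe_deformation(matrix(c(48, 48, 48), 1), matrix(c(5, -4, 3), 1), 40)
  pts <- expand.grid(x = (0:47) * 2, y = (0:47) * 2, z = (0:47) * 2)
  pts <- as.matrix(pts)[, c(1, 2, 3)]
  # build the displacement field of the deformation on the grid
  disp <- forward_map(def, pts) - pts
  fld <- displacement_field(array(disp, c(48, 48, 48, 3)), spacing = c(2, 2, 2))
  neg <- displacement_field(-fld$vectors, spacing = c(2, 2, 2))
  once <- warp_image(ph$image, fld)
  back <- warp_image(once, neg)
  interior <- ph$body
  rng <- diff(range(ph$image$data))
  expect_lt(mean(abs(back$data[interior] - ph$image$data[interior])),
            0.05 * rng)
})
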