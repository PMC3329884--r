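test_that("harmonic map matches direct substitution and fixed lines", {
  # b = 0: identity
  id <- harmonic_deformation(0, 3)
  pts <- matrix(runif(20, -50, 50), 10, 2)
  expect_all_near(forward_map(id, pts), pts, 1e-12)

  # m = 0, b = 0.1 about the origin: x' = 1.1 x
  d0 <- harmonic_deformation(0.1, 0)
  expect_equal(harmonic_displace(c(10, 5), d0)[1, ], c(11, 5))

  # points on the +y axis (x = 0) are fixed
  dm <- harmonic_deformation(0.2, 4)
  ax <- cbind(0, c(-7, 2, 13))
  expect_all_near(forward_map(dm, ax), ax, 1e-12)

  # the centre itself maps to itself (q taken as 0 there)
  expect_all_near(forward_map(dm, matrix(0, 1, 2)), matrix(0, 1, 2), 1e-12)
})

test_that("invalid deformations are rejected before use", {
  expect_error(harmonic_deformation(1.2, 1), "< 1")
  expect_error(harmonic_deformation(0.6, 2), "not invertible")
  expect_error(harmonic_deformation(0.1, -1), "non-negative integer")
  expect_error(lobe_deformation(matrix(0, 1, 3), matrix(c(100, 0, 0), 1), 20),
               "not invertible")
})

test_that("harmonic and lobe inverses undo the forward map", {
  def <- harmonic_deformation(0.13, 2, center = c(50, 40))
  set.seed(24)
  pts <- matrix(runif(400, -60, 160), 200, 2)
  back <- inverse_map(def, forward_map(def, pts))
  expect_all_near(back, pts, 1e-5)

  lob <- lobe_deformation(rbind(c(40, 40, 40), c(80, 70, 60)),
                          rbind(c(10, 4, -8), c(-5, 8, 2)), c(50, 60))
  p3 <- matrix(runif(300, 0, 120), 100, 3)
  expect_all_near(inverse_map(lob, forward_map(lob, p3)), p3, 1e-5)
})

test_that("phantom generation is deterministic and structured", {
  spec <- phantom_spec(dims = c(64, 64), spacing = c(2, 2), n_markers = 0,
                       seed = 7)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$data, b$image$data)

  flat <- phantom_spec(dims = c(64, 64), spacing = c(2, 2),
                       blob_amplitude = 0, seed = 7)
  ph <- generate_phantom(flat)
  expect_setequal(unique(as.numeric(ph$image$data)), c(-1000, 40))

  spec3 <- phantom_spec(dims = c(48, 48, 48), spacing = c(2, 2, 2),
                        n_blobs = 100, n_markers = 20, marker_radius = 3,
                        seed = 8)
  ph3 <- generate_phantom(spec3)
  expect_equal(nrow(ph3$markers), 20L)
  idx <- round(physical_to_voxel(ph3$image, landmark_matrix(ph3$markers, 3)))
  expect_true(all(ph3$body[idx]))
})

test_that("deforming with the identity and a translation behaves exactly", {
  spec <- phantom_spec(dims = c(48, 48), spacing = c(2, 2), n_blobs = 80,
                       n_markers = 5, marker_radius = 4, seed = 9)
  ph <- generate_phantom(spec)
  id <- translation_deformation(c(0, 0, 0))
  sc <- deform_phantom(ph$image, ph$markers, id, body = ph$body)
  expect_all_near(sc$target$data, ph$image$data, 1e-9)
  expect_all_near(sc$truth$vectors, 0, 1e-12)
  expect_identical(sc$markers$x, ph$markers$x)

  tr <- translation_deformation(c(6, -4, 0))
  sct <- deform_phantom(ph$image, ph$markers, tr)
  expect_all_near(sct$markers$x, ph$markers$x + 6, 1e-12)
  expect_all_near(sct$markers$y, ph$markers$y - 4, 1e-12)
  expect_all_near(sct$truth$vectors[, , , 1], -6, 1e-9)
  expect_all_near(sct$truth$vectors[, , , 2], 4, 1e-9)
})

test_that("markers transport analytically under the harmonic warp", {
  spec <- phantom_spec(dims = c(64, 64), spacing = c(2, 2), n_blobs = 100,
                       n_markers = 8, marker_radius = 4, seed = 10)
  ph <- generate_phantom(spec)
  def <- harmonic_deformation(0.1, 2, center = spec$body_center[1:2])
  sc <- deform_phantom(ph$image, ph$markers, def)
  expected <- forward_map(def, landmark_matrix(ph$markers, 2))
  expect_all_near(cbind(sc$markers$x, sc$markers$y), expected, 1e-9)
})

test_that("stored ground truth is self-consistent at displaced markers", {
  spec <- phantom_spec(dims = c(48, 48, 48), spacing = c(2, 2, 2),
                       n_blobs = 100, n_markers = 10, marker_radius = 3,
                       seed = 11)
  ph <- generate_phantom(spec)
  def <- lobe_deformation(matrix(c(48, 48, 48), 1), matrix(c(8, -5, 6), 1), 55)
  sc <- deform_phantom(ph$image, ph$markers, def, body = ph$body)
  # following the truth field back from a displaced marker recovers it
  moved <- landmark_matrix(sc$markers, 3)
  orig <- landmark_matrix(ph$markers, 3)
  for (r in seq_len(nrow(moved))) {
    u <- vapply(1:3, function(c) {
      comp <- sc$truth$vectors[, , , c]
      vol <- volume_image(comp, sc$truth$spacing, sc$truth$origin)
      cpp_interp <- featwarp:::cpp_sample_linear(
        vol$data, as.integer(vol$dims), vol$spacing, vol$origin,
        matrix(moved[r, ], 1), 0)
      cpp_interp[1]
    }, numeric(1))
    expect_all_near(moved[r, ] + u, orig[r, ], 0.05)
  }
})

test_that("3D images reject the 2D harmonic deformation", {
  spec <- phantom_spec(dims = c(32, 32, 32), n_blobs = 10, seed = 1)
  ph <- generate_phantom(spec)
  expect_error(deform_phantom(ph$image, ph$markers,
                              harmonic_deformation(0.1, 1)), "2D")
})
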