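# Independent reference implementations (naive scalar loops) used as
# oracles against the package's vectorized/compiled paths, plus small
# fixture builders.  These deliberately share no code with the package
# internals.

# central-difference gradient with replicated edges, one voxel at a time
naive_gradient <- function(a) {
  d <- dim(a)
  cl <- function(v, n) min(max(v, 1L), n)
  gx <- gy <- gz <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    gx[i, j, k] <- (a[cl(i + 1L, d[1]), j, k] - a[cl(i - 1L, d[1]), j, k]) / 2
    gy[i, j, k] <- (a[i, cl(j + 1L, d[2]), k] - a[i, cl(j - 1L, d[2]), k]) / 2
    if (d[3] > 1L)
      gz[i, j, k] <- (a[i, j, cl(k + 1L, d[3])] - a[i, j, cl(k - 1L, d[3])]) / 2
  }
  list(gx = gx, gy = gy, gz = gz)
}

# descriptor by direct triple loop over the window
naive_descriptor <- function(image, centre, mode2d = FALSE) {
  g <- naive_gradient(image$data)
  ncomp <- if (mode2d) 32L else 192L
  out <- numeric(ncomp)
  zoff <- if (mode2d) 0L else -4:3
  bin_of <- function(c1, c2) {
    ang <- atan2(c2, c1) * 180 / pi
    if (ang < 0) ang <- ang + 360
    b <- floor(ang / 45)
    if (b > 7) b <- 7
    b
  }
  for (dz in zoff) for (dy in -4:3) for (dx in -4:3) {
    i <- centre[1] + dx; j <- centre[2] + dy; k <- centre[3] + dz
    quad <- (dx >= 0) + 2 * (dy >= 0) + if (mode2d) 0 else 4 * (dz >= 0)
    comps <- if (mode2d) list(c(g$gx[i, j, k], g$gy[i, j, k]))
             else list(c(g$gx[i, j, k], g$gy[i, j, k]),
                       c(g$gy[i, j, k], g$gz[i, j, k]),
                       c(g$gx[i, j, k], g$gz[i, j, k]))
    for (p in seq_along(comps)) {
      mag <- sqrt(sum(comps[[p]]^2))
      if (mag > 0) {
        idx <- if (mode2d) quad * 8 + bin_of(comps[[p]][1], comps[[p]][2])
               else quad * 24 + (p - 1) * 8 + bin_of(comps[[p]][1], comps[[p]][2])
        out[idx + 1] <- out[idx + 1] + mag
      }
    }
  }
  out
}

naive_distance <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s
}

# exhaustive forward matcher: all-pairs scalar distances, lexicographic
# tie-breaks, ratio test
naive_match <- function(A, B, b_lex, kappa_threshold) {
  out <- list()
  for (t in seq_len(nrow(A))) {
    S <- vapply(seq_len(nrow(B)), function(g) naive_distance(A[t, ], B[g, ]),
                numeric(1))
    ord <- order(S, b_lex)
    S1 <- S[ord[1]]; S2 <- S[ord[2]]
    kappa <- if (S2 == 0) 0 else S1 / S2
    if (kappa < kappa_threshold)
      out[[length(out) + 1]] <- data.frame(template = t, target = ord[1],
                                           S1 = S1, S2 = S2, kappa = kappa)
  }
  do.call(rbind, out)
}

# Eq.-style TPS evaluation: affine part plus weighted kernel sum, scalars
naive_tps_eval <- function(model, pt) {
  d <- model$d
  out <- numeric(d)
  for (c in seq_len(d)) {
    acc <- model$affine[1, c]
    for (k in seq_len(d)) acc <- acc + model$affine[k + 1, c] * pt[k]
    for (i in seq_len(nrow(model$control_points))) {
      r <- sqrt(sum((model$control_points[i, ] - pt)^2))
      u <- if (r > 0) r^2 * log(r^2) else 0
      acc <- acc + model$weights[i, c] * u
    }
    out[c] <- acc
  }
  out
}

# wrap a plain descriptor matrix as a sift_descriptors object with
# synthetic point metadata (coordinates on a compact grid)
make_desc <- function(mat, mode = "3d", coords = NULL) {
  n <- nrow(mat)
  pts <- data.frame(i = seq_len(n) + 4L, j = rep(5L, n), k = rep(5L, n))
  if (is.null(coords)) coords <- cbind(seq_len(n), rep(0, n), rep(0, n))
  pts$x <- coords[, 1]; pts$y <- coords[, 2]; pts$z <- coords[, 3]
  structure(mat, points = pts, mode = mode,
            class = c("sift_descriptors", "matrix"))
}

# small textured 2D phantom for fast end-to-end tests
small_phantom_2d <- function(seed = 1, dims = c(96, 96)) {
  spec <- phantom_spec(dims = dims, spacing = c(2, 2),
                       body_semiaxes = 0.45 * dims * 2, n_blobs = 250,
                       seed = seed)
  generate_phantom(spec)
}

expect_all_near <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
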