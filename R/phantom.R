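#' Analytic phantom deformations
#'
#' Three deformation families with exact forward maps, analytic marker
#' transport, and numerically inverted backward maps:
#'
#' * `harmonic_deformation(b, m, center)`: the 2D harmonic warp
#'   `x' = (1 + b cos(m q)) x`, `y' = y`, with `q = atan2(y, x)` measured
#'   about `center`.  `b` sets the magnitude and `m` the angular
#'   complexity of the deformation; only the x coordinate is displaced.
#'   At the centre (`x = y = 0`) `q` is taken as 0, where the map is the
#'   identity anyway.  Requires `|b| < 1`; the stricter bound
#'   `|b| (1 + m/2) < 1` guarantees invertibility along x-lines and is
#'   enforced.
#' * `lobe_deformation(centers, amplitudes, sigma)`: a smooth 2D/3D field,
#'   the sum of Gaussian-windowed displacement lobes
#'   `u(x) = sum_k a_k exp(-|x - c_k|^2 / (2 sigma_k^2))`; invertible when
#'   the total slope `sum |a_k| / (sigma_k sqrt(e))` is below 1 (enforced).
#' * `translation_deformation(t)`: a rigid translation, mainly for tests.
#'
#' `forward_map()` transports template-frame points to the target frame;
#' `inverse_map()` numerically inverts it (vectorized bisection for the
#' harmonic radial equation, fixed-point iteration for lobe fields) to a
#' tolerance of `tol` mm.  `harmonic_displace()` is the forward harmonic
#' map on explicit coordinates.
#'
#' @param b dimensionless magnitude parameter, `|b| < 1`.
#' @param m non-negative integer complexity parameter.
#' @param center physical coordinate (mm) about which the polar angle is
#'   measured.
#' @return A deformation object with class `c("harmonic_deformation",
#'   "deformation")` (similarly for the other constructors).
#' @export
harmonic_deformation <- function(b, m, center = c(0, 0)) {
  if (abs(b) >= 1) stop("|b| must be < 1")
  if (m < 0 || m != round(m)) stop("`m` must be a non-negative integer")
  if (abs(b) * (1 + m / 2) >= 1)
    stop(sprintf("harmonic map with b = %g, m = %d is not invertible (|b|(1 + m/2) >= 1)",
                 b, m))
  structure(list(b = b, m = as.integer(m), center = as.numeric(center)[1:2]),
            class = c("harmonic_deformation", "deformation"))
}

#' @rdname harmonic_deformation
#' @param centers `k x d` matrix of lobe centres (mm).
#' @param amplitudes `k x d` matrix of lobe displacement vectors (mm).
#' @param sigma lobe length scale(s), mm (recycled to `k`).
#' @export
lobe_deformation <- function(centers, amplitudes, sigma) {
  centers <- rbind_coerce(centers)
  amplitudes <- rbind_coerce(amplitudes)
  if (!identical(dim(centers), dim(amplitudes)))
    stop("`centers` and `amplitudes` must have the same shape")
  sigma <- rep_len(as.numeric(sigma), nrow(centers))
  if (any(sigma <= 0)) stop("`sigma` must be positive")
  slope <- sum(sqrt(rowSums(amplitudes^2)) / (sigma * sqrt(exp(1))))
  if (slope >= 1)
    stop(sprintf("lobe field is not invertible: total slope %.2f >= 1 (reduce amplitude or increase sigma)",
                 slope))
  structure(list(centers = centers, amplitudes = amplitudes, sigma = sigma,
                 d = ncol(centers)),
            class = c("lobe_deformation", "deformation"))
}

#' @rdname harmonic_deformation
#' @param t translation vector (mm).
#' @export
translation_deformation <- function(t) {
  structure(list(t = as.numeric(t)), class = c("translation_deformation",
                                               "deformation"))
}

#' @rdname harmonic_deformation
#' @param def a deformation object.
#' @param pts `n x d` matrix of physical points (mm), template frame.
#' @export
forward_map <- function(def, pts) UseMethod("forward_map")

#' @rdname harmonic_deformation
#' @param tol inversion tolerance, mm.
#' @export
inverse_map <- function(def, pts, tol = 1e-6) UseMethod("inverse_map")

#' @export
forward_map.harmonic_deformation <- function(def, pts) {
  pts <- rbind_coerce(pts)
  out <- pts
  xr <- pts[, 1] - def$center[1]
  yr <- pts[, 2] - def$center[2]
  q <- ifelse(xr == 0 & yr == 0, 0, atan2(yr, xr))
  out[, 1] <- def$center[1] + (1 + def$b * cos(def$m * q)) * xr
  out
}

#' @rdname harmonic_deformation
#' @param point physical 2D coordinate(s), as for `forward_map()`.
#' @export
harmonic_displace <- function(point, def) forward_map(def, point)

#' @export
inverse_map.harmonic_deformation <- function(def, pts, tol = 1e-6) {
  pts <- rbind_coerce(pts)
  out <- pts
  xp <- pts[, 1] - def$center[1]
  yr <- pts[, 2] - def$center[2]
  b <- abs(def$b)
  # x and x' share their sign and |x| lies in [|x'|/(1+b), |x'|/(1-b)]:
  # the warp factor (1 + b cos(m q)) is within [1-b, 1+b], so g(x) =
  # (1 + b cos(m q(x))) x - x' changes sign across that bracket.  Bisect.
  lo <- pmin(xp / (1 + b), xp / (1 - b))
  hi <- pmax(xp / (1 + b), xp / (1 - b))
  g <- function(x) (1 + def$b * cos(def$m * ifelse(x == 0 & yr == 0, 0,
                                                   atan2(yr, x)))) * x - xp
  glo <- g(lo)
  for (iter in 1:80) {
    if (max(hi - lo) < tol) break
    mid <- (lo + hi) / 2
    gm <- g(mid)
    takelo <- (gm <= 0) == (glo <= 0)
    lo <- ifelse(takelo, mid, lo)
    glo <- ifelse(takelo, gm, glo)
    hi <- ifelse(takelo, hi, mid)
  }
  out[, 1] <- def$center[1] + (lo + hi) / 2
  out[xp == 0, 1] <- def$center[1]
  out
}

lobe_displacement <- function(def, pts) {
  disp <- matrix(0, nrow(pts), def$d)
  for (k in seq_len(nrow(def$centers))) {
    r2 <- rowSums(sweep(pts[, seq_len(def$d), drop = FALSE], 2,
                        def$centers[k, ], "-")^2)
    w <- exp(-r2 / (2 * def$sigma[k]^2))
    disp <- disp + outer(w, def$amplitudes[k, ])
  }
  disp
}

#' @export
forward_map.lobe_deformation <- function(def, pts) {
  pts <- rbind_coerce(pts)
  out <- pts
  sel <- seq_len(def$d)
  out[, sel] <- pts[, sel, drop = FALSE] +
    lobe_displacement(def, pts[, sel, drop = FALSE])
  out
}

#' @export
inverse_map.lobe_deformation <- function(def, pts, tol = 1e-6) {
  pts <- rbind_coerce(pts)
  sel <- seq_len(def$d)
  target <- pts[, sel, drop = FALSE]
  x <- target
  for (iter in 1:200) {
    xn <- target - lobe_displacement(def, x)
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) break
  }
  out <- pts
  out[, sel] <- x
  out
}

#' @export
forward_map.translation_deformation <- function(def, pts) {
  pts <- rbind_coerce(pts)
  sweep(pts, 2, rep_len(def$t, ncol(pts)), "+")
}

#' @export
inverse_map.translation_deformation <- function(def, pts, tol = 1e-6) {
  pts <- rbind_coerce(pts)
  sweep(pts, 2, rep_len(def$t, ncol(pts)), "-")
}

## --- Phantom specification and generation ------------------------------

#' Specify a textured digital phantom
#'
#' Describes a CT-like test object: an elliptical (2D) or ellipsoidal (3D)
#' "body" of soft-tissue intensity on an air background, filled with a
#' smooth random blob texture (so gradient features exist everywhere inside
#' the body), optionally with embedded rigid spherical markers of known
#' centre, radius, and contrast.  Everything is deterministic given the
#' seed.
#'
#' @param dims grid shape, length 2 (single slice) or 3.
#' @param spacing voxel size, mm.
#' @param body_semiaxes ellipse/ellipsoid semi-axes (mm); default 82% of
#'   the half field of view.
#' @param body_center body centre (mm); default the grid centre.
#' @param body_intensity,background base intensities (water-like 40 over
#'   air-like -1000 by default).
#' @param n_blobs,blob_amplitude,blob_scale texture parameters: number of
#'   Gaussian blobs, absolute amplitude range (intensity units; each blob
#'   draws uniformly from it with a random sign), and length-scale range
#'   (mm; log-uniform per blob).  The defaults give dense multi-scale
#'   structure -- several overlapping blobs inside every 16 mm descriptor
#'   window -- which is what makes gradient orientation signatures
#'   discriminative, as heterogeneous soft-tissue texture does in real CT.
#' @param n_markers number of spherical markers to embed (0 for none).
#' @param marker_radius,marker_contrast marker size (mm) and intensity
#'   added over the body base.
#' @param noise_sd additive Gaussian noise, intensity units.
#' @param seed RNG seed making the phantom reproducible.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dims, spacing = c(2, 2, 2), body_semiaxes = NULL,
                         body_center = NULL, body_intensity = 40,
                         background = -1000, n_blobs = 500,
                         blob_amplitude = c(60, 180), blob_scale = c(4, 16),
                         n_markers = 0, marker_radius = 5,
                         marker_contrast = 400, noise_sd = 0, seed = 1) {
  dims <- as.integer(dims)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  if (length(dims) != 3L) stop("`dims` must have length 2 or 3")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  is2d <- dims[3] == 1L
  fov <- dims * spacing
  if (is.null(body_center)) body_center <- (dims - 1) / 2 * spacing
  if (is.null(body_semiaxes)) {
    body_semiaxes <- 0.41 * fov
    if (is2d) body_semiaxes <- body_semiaxes[1:2]
  }
  body_semiaxes <- as.numeric(body_semiaxes)
  if (length(body_semiaxes) == 2L) body_semiaxes <- c(body_semiaxes, Inf)
  structure(list(dims = dims, spacing = spacing, is2d = is2d,
                 body_semiaxes = body_semiaxes,
                 body_center = as.numeric(body_center)[1:3],
                 body_intensity = body_intensity, background = background,
                 n_blobs = as.integer(n_blobs),
                 blob_amplitude = range(abs(blob_amplitude)),
                 blob_scale = range(blob_scale),
                 n_markers = as.integer(n_markers),
                 marker_radius = marker_radius,
                 marker_contrast = marker_contrast,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a textured digital phantom
#'
#' Renders the [phantom_spec()]: body ellipse over background, Gaussian
#' blob texture inside the body, markers as spheres with a one-voxel
#' linear edge blend (so marker boundaries give clean sub-voxel gradient
#' structure), and optional additive Gaussian noise.  Marker centres are
#' rejection-sampled inside 80% of the body with a minimum separation of
#' four marker radii; an error is raised if the requested number cannot be
#' placed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (a [volume_image()]), `markers` (a
#'   [landmark_set()] of marker centres, mm), and `body` (logical mask
#'   array of in-body voxels).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  with_seed(spec$seed, {
    d <- spec$dims
    img <- volume_image(array(spec$background, d), spec$spacing)
    xs <- (seq_len(d[1]) - 1) * spec$spacing[1]
    ys <- (seq_len(d[2]) - 1) * spec$spacing[2]
    zs <- (seq_len(d[3]) - 1) * spec$spacing[3]
    ex <- (xs - spec$body_center[1]) / spec$body_semiaxes[1]
    ey <- (ys - spec$body_center[2]) / spec$body_semiaxes[2]
    ez <- if (is.finite(spec$body_semiaxes[3]))
      (zs - spec$body_center[3]) / spec$body_semiaxes[3] else rep(0, d[3])
    rr <- outer(outer(ex^2, ey^2, "+"), ez^2, "+")
    body <- rr <= 1
    a <- img$data
    a[body] <- spec$body_intensity

    # blob texture, each blob evaluated only on its local 3-sigma box
    if (spec$n_blobs > 0 && any(spec$blob_amplitude > 0)) {
      centers <- sample_in_body(spec$n_blobs, spec, margin = 0)
      amps <- sample(c(-1, 1), spec$n_blobs, replace = TRUE) *
        runif(spec$n_blobs, spec$blob_amplitude[1], spec$blob_amplitude[2])
      sig <- exp(runif(spec$n_blobs, log(spec$blob_scale[1]),
                       log(spec$blob_scale[2])))
      for (b in seq_len(spec$n_blobs))
        a <- add_blob(a, centers[b, ], amps[b], sig[b], spec)
      a[!body] <- spec$background
    }

    markers <- matrix(numeric(0), 0, 3)
    if (spec$n_markers > 0) {
      markers <- sample_in_body(spec$n_markers, spec, margin = 0.2,
                                min_sep = 4 * spec$marker_radius)
      for (mk in seq_len(nrow(markers)))
        a <- add_marker(a, markers[mk, ], spec)
    }
    if (spec$noise_sd > 0) a <- a + rnorm(length(a), 0, spec$noise_sd)
    list(image = volume_image(a, spec$spacing),
         markers = landmark_set(markers,
                                if (nrow(markers)) paste0("marker", seq_len(nrow(markers))) else NULL,
                                dim = if (spec$is2d) 2L else 3L),
         body = body)
  })
}

sample_in_body <- function(n, spec, margin = 0, min_sep = 0) {
  semi <- spec$body_semiaxes * (1 - margin)
  if (spec$is2d) semi[3] <- 0
  pts <- matrix(NA_real_, n, 3)
  got <- 0L
  for (try in seq_len(20000L)) {
    u <- runif(3, -1, 1)
    if (spec$is2d) u[3] <- 0
    if (sum(u^2) > 1) next
    p <- spec$body_center + u * ifelse(is.finite(semi), semi, 0)
    if (spec$is2d) p[3] <- spec$body_center[3]
    if (min_sep > 0 && got > 0) {
      dmin <- min(sqrt(rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, p)^2)))
      if (dmin < min_sep) next
    }
    got <- got + 1L
    pts[got, ] <- p
    if (got == n) break
  }
  if (got < n)
    stop(sprintf("could only place %d of %d points inside the body (reduce count, radius, or separation)",
                 got, n))
  pts
}

# evaluate a Gaussian blob on its local 3-sigma voxel box
add_blob <- function(a, center, amp, sigma, spec) {
  d <- spec$dims
  vi <- function(ax) {
    lo <- max(1L, floor((center[ax] - 3 * sigma) / spec$spacing[ax]) + 1L)
    hi <- min(d[ax], ceiling((center[ax] + 3 * sigma) / spec$spacing[ax]) + 1L)
    if (lo > hi) integer(0) else lo:hi
  }
  ix <- vi(1); iy <- vi(2)
  iz <- if (spec$is2d) 1L else vi(3)
  if (!length(ix) || !length(iy) || !length(iz)) return(a)
  dx <- ((ix - 1) * spec$spacing[1] - center[1])^2
  dy <- ((iy - 1) * spec$spacing[2] - center[2])^2
  dz <- ((iz - 1) * spec$spacing[3] - center[3])^2
  if (spec$is2d) dz <- 0
  r2 <- outer(outer(dx, dy, "+"), dz, "+")
  a[ix, iy, iz] <- a[ix, iy, iz, drop = FALSE] + amp * exp(-r2 / (2 * sigma^2))
  a
}

# rigid sphere with a one-voxel linear edge blend
add_marker <- function(a, center, spec) {
  d <- spec$dims
  r <- spec$marker_radius
  edge <- max(spec$spacing[1:2])
  vi <- function(ax) {
    lo <- max(1L, floor((center[ax] - r - edge) / spec$spacing[ax]) + 1L)
    hi <- min(d[ax], ceiling((center[ax] + r + edge) / spec$spacing[ax]) + 1L)
    lo:hi
  }
  ix <- vi(1); iy <- vi(2)
  iz <- if (spec$is2d) 1L else vi(3)
  dx <- ((ix - 1) * spec$spacing[1] - center[1])^2
  dy <- ((iy - 1) * spec$spacing[2] - center[2])^2
  dz <- ((iz - 1) * spec$spacing[3] - center[3])^2
  if (spec$is2d) dz <- 0
  rr <- sqrt(outer(outer(dx, dy, "+"), dz, "+"))
  w <- pmin(pmax((r + edge / 2 - rr) / edge, 0), 1)
  val <- spec$body_intensity + spec$marker_contrast
  a[ix, iy, iz] <- a[ix, iy, iz, drop = FALSE] * (1 - w) + val * w
  a
}

#' Deform a phantom with an analytically known map
#'
#' Produces the target image, the transported markers, and the exact
#' ground-truth displacement field for a registration experiment.  The
#' target is the phantom resampled through the numerically inverted
#' forward map (backward sampling, linear interpolation); markers are moved
#' analytically by the forward map; the ground-truth field is stored on
#' the target grid in the same target-to-template convention as
#' registration output (`u(x) = phi^-1(x) - x`), so estimated and true
#' fields are directly comparable by subtraction.  Invertibility of the
#' requested deformation is checked at construction time (see
#' [harmonic_deformation()]).
#'
#' @param image the template [volume_image()] (from [generate_phantom()]).
#' @param markers a [landmark_set()] of template-frame marker positions
#'   (may be empty).
#' @param deformation a `deformation` object.
#' @param body optional logical body mask; when supplied, the deformed
#'   body mask is returned too.
#' @param fill out-of-bounds fill value for resampling (default: image
#'   minimum).
#' @param tol inversion tolerance, mm.
#' @return A list with `target` ([volume_image()]), `markers`
#'   (transported [landmark_set()]), `truth` ([displacement_field()]), and
#'   `body` (deformed mask, or `NULL`).
#' @export
deform_phantom <- function(image, markers, deformation, body = NULL,
                           fill = NULL, tol = 1e-6) {
  stopifnot_volume(image)
  if (!inherits(deformation, "deformation"))
    stop("`deformation` must be a deformation object")
  if (inherits(deformation, "harmonic_deformation") && !image$is2d)
    stop("the harmonic deformation is 2D; use lobe_deformation() for volumes")
  if (is.null(fill)) fill <- min(image$data)
  d <- if (image$is2d) 2L else 3L
  pts <- grid_coordinates(image)
  back <- inverse_map(deformation, pts[, seq_len(d), drop = FALSE], tol = tol)
  sample_pts <- pts
  sample_pts[, seq_len(d)] <- back
  vals <- cpp_sample_linear(image$data, as.integer(image$dims),
                            image$spacing, image$origin, sample_pts, fill)
  target <- volume_image(array(vals, image$dims), image$spacing, image$origin)
  truth <- displacement_field(
    array(back - pts[, seq_len(d), drop = FALSE], c(image$dims, d)),
    image$spacing, image$origin)
  moved <- markers
  if (!is.null(markers) && nrow(markers) > 0) {
    mm <- landmark_matrix(markers, d)
    fm <- forward_map(deformation, mm)
    coords <- cbind(fm, if (d == 2L) markers$z)[, 1:3, drop = FALSE]
    moved <- landmark_set(coords, markers$label, dim = d)
  }
  body_t <- NULL
  if (!is.null(body)) {
    bvals <- cpp_sample_linear(as.numeric(body), as.integer(image$dims),
                               image$spacing, image$origin, sample_pts, 0)
    body_t <- array(bvals >= 0.5, image$dims)
  }
  list(target = target, markers = moved, truth = truth, body = body_t)
}
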