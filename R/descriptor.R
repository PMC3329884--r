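#' Gradient orientation-histogram descriptors
#'
#' Builds the SIFT-style signature of each feature point.  The 8x8x8 voxel
#' window centred on the point (spanning offsets -4..3 along each axis) is
#' split into eight 4x4x4 octants; within each octant, and for each of the
#' three coordinate planes (xy, yz, zx), the in-plane projection of every
#' voxel's gradient is binned by its in-plane angle into eight 45-degree
#' bins covering \[0, 360) degrees (half-open: an angle exactly on an edge
#' goes to the higher bin), accumulating the in-plane gradient magnitude.
#' That yields 8 octants x 3 planes x 8 bins = 192 non-negative components,
#' ordered octant-major, then plane (xy, yz, zx), then bin.  Zero-magnitude
#' projections contribute nothing.
#'
#' For 2D images the window is 8x8, split into four 4x4 quadrants with the
#' single xy plane: 32 components, flagged so 2D and 3D descriptors are
#' never compared.
#'
#' @param image a [volume_image()].
#' @param points a `feature_points` data frame from
#'   [detect_feature_points()], or any data frame with columns `i, j, k`
#'   (and ideally `x, y, z`); every point must be at least 4 voxels from
#'   each image face.
#' @param weighting `"magnitude"` (default, classical SIFT convention) or
#'   `"count"` to accumulate 1 per nonzero projection.
#' @param normalize if `TRUE`, scale each descriptor to unit L2 norm
#'   (default off: raw histograms are compared).
#' @param gradient optional precomputed [compute_gradient()] result.
#' @return An object of class `sift_descriptors`: an `n x 192` (3D) or
#'   `n x 32` (2D) matrix with attributes `points` (the input data frame,
#'   with physical coordinates filled in) and `mode` (`"3d"` or `"2d"`).
#' @export
compute_descriptors <- function(image, points,
                                weighting = c("magnitude", "count"),
                                normalize = FALSE, gradient = NULL) {
  stopifnot_volume(image)
  weighting <- match.arg(weighting)
  pts <- as.data.frame(points)
  if (!all(c("i", "j", "k") %in% names(pts)))
    stop("`points` must have columns i, j, k")
  d <- image$dims
  ijk <- as.matrix(pts[, c("i", "j", "k")])
  storage.mode(ijk) <- "integer"
  lo_ok <- ijk[, 1] >= 5L & ijk[, 2] >= 5L & (image$is2d | ijk[, 3] >= 5L)
  hi_ok <- ijk[, 1] <= d[1] - 3L & ijk[, 2] <= d[2] - 3L &
           (image$is2d | ijk[, 3] <= d[3] - 3L)
  bad <- which(!(lo_ok & hi_ok))
  if (length(bad))
    stop(sprintf("descriptor window out of bounds for point %d at (%d, %d, %d)",
                 bad[1], ijk[bad[1], 1], ijk[bad[1], 2], ijk[bad[1], 3]))
  if (is.null(gradient)) gradient <- compute_gradient(image)
  desc <- cpp_descriptors(gradient$gx, gradient$gy, gradient$gz,
                          as.integer(d), ijk, image$is2d,
                          weighting == "count")
  if (normalize) {
    nrm <- sqrt(rowSums(desc^2))
    nz <- nrm > 0
    desc[nz, ] <- desc[nz, , drop = FALSE] / nrm[nz]
  }
  if (!all(c("x", "y", "z") %in% names(pts))) {
    xyz <- voxel_to_physical(image, ijk)
    pts$x <- xyz[, 1]; pts$y <- xyz[, 2]; pts$z <- xyz[, 3]
  }
  structure(desc, points = pts, mode = if (image$is2d) "2d" else "3d",
            weighting = weighting, class = c("sift_descriptors", "matrix"))
}

#' @rdname compute_descriptors
#' @param point a single feature point (one-row data frame or a length-3
#'   vector of voxel indices `(i, j, k)`).
#' @param ... passed on to `compute_descriptors()`.
#' @return `compute_descriptor()` returns the descriptor of one point as a
#'   numeric vector of length 192 (3D) or 32 (2D).
#' @export
compute_descriptor <- function(image, point, ...) {
  if (is.numeric(point) && is.null(dim(point)))
    point <- data.frame(i = point[1], j = point[2],
                        k = if (length(point) >= 3) point[3] else 1)
  drop(unclass(compute_descriptors(image, point, ...))[1, ])
}

descriptor_mode <- function(x) {
  attr(x, "mode") %||% if (NCOL(x) == 32 || length(x) == 32) "2d" else "3d"
}

#' Least-squares distance between two descriptors
#'
#' The sum over all components of squared differences -- non-negative,
#' symmetric, and zero exactly when the descriptors are componentwise
#' equal.  2D and 3D descriptors are never comparable.
#'
#' @param a,b descriptor vectors (or single-row `sift_descriptors`).
#' @return A non-negative scalar.
#' @export
descriptor_distance <- function(a, b) {
  if (descriptor_mode(a) != descriptor_mode(b))
    stop("cannot compare 2D and 3D descriptors")
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("descriptor lengths differ")
  sum((a - b)^2)
}

# Full pairwise squared-L2 distance matrix between descriptor sets,
# computed via the polarization identity with BLAS.
descriptor_distance_matrix <- function(A, B) {
  A <- unclass(A); B <- unclass(B)
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  D <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}
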