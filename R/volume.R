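#' Scalar image on a regular grid
#'
#' The basic image container: a 2D or 3D scalar array together with its
#' voxel spacing and the physical coordinate of the first voxel.  All
#' registration math in the package is done in physical millimetres;
#' `spacing` and `origin` define the (axis-aligned) mapping between voxel
#' indices and physical space.  2D images are carried as single-slice 3D
#' arrays and flagged, so descriptor construction can switch to its 2D mode.
#'
#' Voxel indices are 1-based (the R convention); the physical coordinate of
#' voxel `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`.  Direction
#' cosines are not supported: grids are assumed axis-aligned, and image
#' files with a non-identity orientation are rejected on read.
#'
#' @param data numeric matrix (2D image) or 3D array of intensities
#'   (HU-like arbitrary units).
#' @param spacing per-axis voxel size in mm (length 2 or 3, all > 0).
#' @param origin physical coordinate (mm) of voxel `(1, 1, 1)`.
#' @return An object of class `volume_image` with fields `data` (always a
#'   3D array), `spacing`, `origin`, `dims` and `is2d`.
#' @examples
#' img <- volume_image(matrix(rnorm(64), 8, 8), spacing = c(2, 2))
#' img$is2d
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a matrix or a 3D array")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  if (length(origin) == 2L) origin <- c(origin, 0)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 2 or 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 2 or 3 finite values")
  structure(
    list(data = data, spacing = spacing, origin = origin,
         dims = dim(data), is2d = dim(data)[3] == 1L),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s grid %s, spacing %s mm, origin %s mm\n",
              if (x$is2d) "2D" else "3D",
              paste(x$dims, collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) x$dims

stopifnot_volume <- function(x, what = "image") {
  if (!inherits(x, "volume_image"))
    stop(sprintf("`%s` must be a volume_image", what))
  invisible(x)
}

#' Convert between voxel indices and physical coordinates
#'
#' `voxel_to_physical()` maps (possibly fractional) 1-based voxel indices to
#' physical mm; `physical_to_voxel()` is its exact inverse.  On-grid indices
#' round-trip to themselves, making the conversion a bijection on the grid.
#'
#' @param image a [volume_image()] (or anything with `spacing`/`origin`).
#' @param idx n x 3 matrix (or length-3 vector) of voxel indices.
#' @param pts n x 3 matrix (or length-3 vector) of physical coordinates (mm).
#' @return A numeric matrix with one row per input point.
#' @export
voxel_to_physical <- function(image, idx) {
  idx <- rbind_coerce(idx)
  sweep(sweep(idx - 1, 2, image$spacing[seq_len(ncol(idx))], "*"),
        2, image$origin[seq_len(ncol(idx))], "+")
}

#' @rdname voxel_to_physical
#' @export
physical_to_voxel <- function(image, pts) {
  pts <- rbind_coerce(pts)
  sweep(sweep(pts, 2, image$origin[seq_len(ncol(pts))], "-"),
        2, image$spacing[seq_len(ncol(pts))], "/") + 1
}

rbind_coerce <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.matrix(x)
}

#' Dense displacement vector field
#'
#' A per-voxel displacement field on the same kind of regular grid as a
#' [volume_image()].  Displacements are stored in physical millimetres.  The
#' package convention (used by both registration output and phantom ground
#' truth, so the two are directly comparable) is *target to template*: the
#' vector at a target-grid voxel points to the corresponding location in the
#' template image, i.e. the field supports backward warping.
#'
#' @param vectors 4D array `(nx, ny, nz, d)` of displacement components
#'   (mm); `d` must equal the grid dimensionality (2 for single-slice
#'   grids, 3 otherwise) and all values must be finite.
#' @param spacing,origin grid geometry as for [volume_image()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L)
    stop("`vectors` must be a 4D array (nx, ny, nz, components)")
  storage.mode(vectors) <- "double"
  dims <- dim(vectors)[1:3]
  d <- dim(vectors)[4]
  expected <- if (dims[3] == 1L) 2L else 3L
  if (d != expected)
    stop(sprintf("field on a %s grid must have %d components, got %d",
                 paste(dims, collapse = "x"), expected, d))
  if (!all(is.finite(vectors)))
    stop("displacement field contains non-finite values")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  if (length(origin) == 2L) origin <- c(origin, 0)
  structure(
    list(vectors = vectors, spacing = spacing, origin = origin,
         dims = dims, d = d, is2d = dims[3] == 1L),
    class = "displacement_field"
  )
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- field_magnitude(x)
  cat(sprintf(
    "<displacement_field> %dD on %s grid, spacing %s mm\n  |u|: mean %.3g, max %.3g mm\n",
    x$d, paste(x$dims, collapse = "x"),
    paste(format(x$spacing), collapse = ", "),
    mean(mag), max(mag)))
  invisible(x)
}

#' Per-voxel magnitude of a displacement field
#'
#' @param field a [displacement_field()].
#' @return 3D array of vector magnitudes (mm).
#' @export
field_magnitude <- function(field) {
  acc <- array(0, field$dims)
  for (c in seq_len(field$d)) {
    comp <- field$vectors[, , , c, drop = FALSE]
    dim(comp) <- field$dims
    acc <- acc + comp^2
  }
  sqrt(acc)
}

#' Landmark set in physical coordinates
#'
#' A light container for named points in physical mm: control points for
#' thin-plate-spline fitting, phantom marker centres, or any other labelled
#' positions.  Stored as a data frame with columns `label, x, y, z`.
#'
#' @param points n x 2 or n x 3 numeric matrix of coordinates (mm); a 2D
#'   matrix gets `z = 0`.
#' @param labels optional character labels, unique when present; defaults
#'   to `p1, p2, ...`.
#' @param dim spatial dimensionality the set is meant for (2 or 3);
#'   defaults to the number of columns supplied.
#' @return A data frame of class `landmark_set` with a `dim` attribute.
#' @export
landmark_set <- function(points, labels = NULL, dim = NULL) {
  points <- rbind_coerce(points)
  if (ncol(points) == 2L) {
    if (is.null(dim)) dim <- 2L
    points <- cbind(points, 0)
  }
  if (ncol(points) != 3L) stop("`points` must have 2 or 3 columns")
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop("landmark coordinates must be finite")
  if (is.null(dim)) dim <- 3L
  if (is.null(labels)) labels <- if (nrow(points)) paste0("p", seq_len(nrow(points))) else character(0)
  labels <- as.character(labels)
  if (length(labels) != nrow(points))
    stop("`labels` length must match the number of points")
  if (anyDuplicated(labels)) stop("landmark labels must be unique")
  out <- data.frame(label = labels, x = points[, 1], y = points[, 2],
                    z = points[, 3], stringsAsFactors = FALSE)
  class(out) <- c("landmark_set", "data.frame")
  attr(out, "spdim") <- as.integer(dim)
  out
}

landmark_matrix <- function(set, d = NULL) {
  if (is.null(d)) d <- attr(set, "spdim") %||% 3L
  as.matrix(set[, c("x", "y", "z")[seq_len(d)], drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
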