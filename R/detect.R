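#' Per-voxel intensity gradient by central differences
#'
#' The gradient component along each axis at voxel `(i,j,k)` is half the
#' difference of the two axis neighbours, e.g.
#' `(I[i+1,j,k] - I[i-1,j,k]) / 2` along x.  Boundary voxels use
#' replicated-edge (clamped) neighbours.  Components are in image units per
#' voxel step (not spacing-scaled), so descriptors built from them describe
#' the image lattice; for a 2D image the z component is identically zero.
#'
#' @param image a [volume_image()] with at least 3 voxels along every
#'   non-degenerate axis.
#' @return A list with 3D arrays `gx`, `gy`, `gz`.
#' @export
compute_gradient <- function(image) {
  stopifnot_volume(image)
  d <- image$dims
  for (ax in 1:2)
    if (d[ax] < 3) stop(sprintf("axis %d has %d voxels; need at least 3", ax, d[ax]))
  if (!image$is2d && d[3] < 3)
    stop(sprintf("axis 3 has %d voxels; need at least 3", d[3]))
  a <- image$data
  shifted <- function(dx, dy, dz) {
    ix <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    iz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    a[ix, iy, iz, drop = FALSE]
  }
  gx <- (shifted(1L, 0L, 0L) - shifted(-1L, 0L, 0L)) / 2
  gy <- (shifted(0L, 1L, 0L) - shifted(0L, -1L, 0L)) / 2
  gz <- if (image$is2d) array(0, d)
        else (shifted(0L, 0L, 1L) - shifted(0L, 0L, -1L)) / 2
  list(gx = gx, gy = gy, gz = gz)
}

#' Feature-detection configuration
#'
#' Controls which voxels become candidate feature points.  The intensity
#' window selects the tissue of interest, following the tissue-thresholding
#' practice for CT-like units: bone lies above 100, soft tissue such as
#' pancreas between 0 and 100, so the default `(0, Inf)` keeps soft tissue
#' and bone while excluding air and the ambiguous air-tissue
#' partial-volume shell (whose long self-similar boundary edge otherwise
#' produces unreliable matches).  Saliency is the sum of squared gradient
#' magnitudes over the 3x3x3 neighbourhood; when `min_saliency` is `NULL`
#' the threshold is set to the `saliency_quantile` quantile of in-window
#' saliency, keeping the most structured 40 percent of candidate voxels by
#' default -- dense enough that nearly every true correspondence has a
#' detected counterpart, while `nms_radius` and `max_points` keep the set
#' well spread and bounded.
#'
#' @param intensity_window length-2 numeric `(low, high)`, image units.
#' @param min_saliency absolute saliency threshold, or `NULL` to derive it
#'   from `saliency_quantile`.
#' @param saliency_quantile quantile of in-window saliency used when
#'   `min_saliency` is `NULL` (default 0.6).
#' @param nms_radius physical radius (mm) for non-maximum suppression.
#' @param max_points cap on returned points (strongest kept).
#' @param border_margin voxels excluded at every image face; must be at
#'   least 4 so the 8x8(x8) descriptor window always fits.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(intensity_window = c(0, Inf),
                             min_saliency = NULL,
                             saliency_quantile = 0.6,
                             nms_radius = 3,
                             max_points = 10000,
                             border_margin = 4) {
  if (length(intensity_window) != 2L || intensity_window[1] > intensity_window[2])
    stop("`intensity_window` must be (low, high) with low <= high")
  if (nms_radius < 0) stop("`nms_radius` must be >= 0")
  if (max_points < 1) stop("`max_points` must be >= 1")
  if (border_margin < 4)
    stop("`border_margin` must be >= 4 (half the descriptor window)")
  if (!is.null(min_saliency) && min_saliency < 0)
    stop("`min_saliency` must be >= 0")
  if (saliency_quantile < 0 || saliency_quantile >= 1)
    stop("`saliency_quantile` must be in [0, 1)")
  structure(list(intensity_window = as.numeric(intensity_window),
                 min_saliency = min_saliency,
                 saliency_quantile = saliency_quantile,
                 nms_radius = nms_radius,
                 max_points = as.integer(max_points),
                 border_margin = as.integer(border_margin)),
            class = "detection_config")
}

box_neighbourhood_sum <- function(a, is2d) {
  d <- dim(a)
  out <- array(0, d)
  zr <- if (is2d) 0L else -1:1
  for (dz in zr) for (dy in -1:1) for (dx in -1:1) {
    ix <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    iz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out + a[ix, iy, iz, drop = FALSE]
  }
  out
}

#' Detect feature points from local gradient energy
#'
#' Candidate voxels must lie inside the intensity window and at least
#' `border_margin` voxels from every face.  Each candidate's saliency is
#' the sum of squared gradient magnitudes over its 3x3x3 neighbourhood;
#' candidates below the saliency threshold are dropped, the rest are
#' non-maximum suppressed within `nms_radius` (mm) in descending saliency
#' order (ties broken by lexicographic `(i,j,k)` for determinism) and
#' truncated at `max_points`.  The result is sorted by descending saliency.
#'
#' @param image a [volume_image()].
#' @param config a [detection_config()].
#' @return A data frame of class `feature_points` with columns `i, j, k`
#'   (voxel index), `x, y, z` (mm), `saliency`, `intensity`; empty (with a
#'   warning) when nothing passes the thresholds.
#' @export
detect_feature_points <- function(image, config = detection_config()) {
  stopifnot_volume(image)
  if (!inherits(config, "detection_config"))
    stop("`config` must be a detection_config")
  d <- image$dims
  g <- compute_gradient(image)
  sal <- box_neighbourhood_sum(g$gx^2 + g$gy^2 + g$gz^2, image$is2d)

  m <- config$border_margin
  ok_i <- seq_len(d[1]) >= (m + 1L) & seq_len(d[1]) <= (d[1] - m)
  ok_j <- seq_len(d[2]) >= (m + 1L) & seq_len(d[2]) <= (d[2] - m)
  ok_k <- if (image$is2d) rep(TRUE, d[3])
          else seq_len(d[3]) >= (m + 1L) & seq_len(d[3]) <= (d[3] - m)
  interior <- outer(outer(ok_i, ok_j, "&"), ok_k, "&")
  win <- image$data >= config$intensity_window[1] &
         image$data <= config$intensity_window[2]
  eligible <- interior & win

  thr <- config$min_saliency
  if (is.null(thr)) {
    vals <- sal[eligible]
    thr <- if (length(vals)) stats::quantile(vals, config$saliency_quantile,
                                             names = FALSE) else Inf
  }
  cand <- which(eligible & sal >= thr & sal > 0)
  if (length(cand) == 0L) {
    warning("no feature points detected; relax the intensity window or saliency threshold")
    return(empty_feature_points())
  }
  ijk <- arrayInd(cand, d)
  s <- sal[cand]
  ord <- order(-s, ijk[, 1], ijk[, 2], ijk[, 3])
  ijk <- ijk[ord, , drop = FALSE]
  s <- s[ord]
  xyz <- voxel_to_physical(image, ijk)
  keep <- cpp_nms(xyz, config$nms_radius, config$max_points)
  out <- data.frame(i = ijk[keep, 1], j = ijk[keep, 2], k = ijk[keep, 3],
                    x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
                    saliency = s[keep],
                    intensity = image$data[cand[ord][keep]])
  class(out) <- c("feature_points", "data.frame")
  out
}

empty_feature_points <- function() {
  out <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                    x = numeric(0), y = numeric(0), z = numeric(0),
                    saliency = numeric(0), intensity = numeric(0))
  class(out) <- c("feature_points", "data.frame")
  out
}
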