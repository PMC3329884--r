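#' Per-voxel registration error against ground truth
#'
#' The pointwise magnitude of the vector difference between an estimated
#' and a true displacement field on the same grid.  Evaluation is normally
#' restricted to a body mask: a feature-based registration places no
#' control points in empty background, so errors there are meaningless
#' extrapolation and would swamp the statistics.
#'
#' @param estimated,truth [displacement_field()]s on identical grids.
#' @param mask optional logical array (grid shape); voxels outside it are
#'   marked not-evaluated (`NA`).
#' @return A 3D array of error magnitudes (mm), `NA` outside the mask.
#' @export
error_field <- function(estimated, truth, mask = NULL) {
  for (f in list(estimated, truth))
    if (!inherits(f, "displacement_field"))
      stop("`estimated` and `truth` must be displacement_fields")
  if (!identical(estimated$dims, truth$dims) ||
      max(abs(estimated$spacing - truth$spacing)) > 1e-9 ||
      max(abs(estimated$origin - truth$origin)) > 1e-9)
    stop("estimated and truth fields are on different grids")
  if (estimated$d != truth$d)
    stop("fields have different component counts")
  diff <- matrix(estimated$vectors - truth$vectors, ncol = estimated$d)
  err <- array(sqrt(rowSums(diff^2)), estimated$dims)
  if (!is.null(mask)) {
    if (!identical(dim(mask), estimated$dims))
      stop("`mask` shape does not match the field grid")
    err[!mask] <- NA_real_
  }
  err
}

#' Summarize registration errors
#'
#' Aggregates a per-voxel error map (and optionally marker residuals) into
#' the standard report: mean and maximum error over evaluated voxels, the
#' fraction of voxels exceeding each threshold, and -- when marker sets are
#' supplied -- each marker's residual (the distance between its
#' ground-truth-mapped and registration-mapped positions) with the
#' fraction of markers below each threshold.
#'
#' @param errors numeric array/vector of per-voxel errors (mm), `NA` for
#'   not-evaluated voxels; must contain at least one evaluated voxel.
#' @param markers_true,markers_mapped optional aligned [landmark_set()]s:
#'   the true template-frame marker positions and the positions the
#'   registration maps the (deformed) markers to.
#' @param thresholds error thresholds, mm; defaults 2 mm (marker
#'   criterion) and 10 mm (gross-error criterion).
#' @return A list of class `error_report`: `mean_error`, `max_error`,
#'   `n_evaluated`, `exceedance` (named fraction per threshold),
#'   `marker_errors`, `fraction_markers_below` (named fraction per
#'   threshold, `NULL` without markers).
#' @export
summarize_errors <- function(errors, markers_true = NULL,
                             markers_mapped = NULL, thresholds = c(2, 10)) {
  vals <- as.numeric(errors)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no evaluated voxels (empty mask?)")
  exceed <- vapply(thresholds, function(t) mean(vals > t), numeric(1))
  names(exceed) <- paste0(">", thresholds, "mm")
  marker_errors <- NULL
  frac_below <- NULL
  if (!is.null(markers_true) && !is.null(markers_mapped)) {
    if (nrow(markers_true) != nrow(markers_mapped))
      stop("marker sets must be aligned (equal counts)")
    d <- min(attr(markers_true, "spdim") %||% 3L,
             attr(markers_mapped, "spdim") %||% 3L)
    delta <- landmark_matrix(markers_mapped, d) - landmark_matrix(markers_true, d)
    marker_errors <- sqrt(rowSums(delta^2))
    names(marker_errors) <- markers_true$label
    frac_below <- vapply(thresholds, function(t) mean(marker_errors < t),
                         numeric(1))
    names(frac_below) <- paste0("<", thresholds, "mm")
  }
  structure(list(mean_error = mean(vals), max_error = max(vals),
                 n_evaluated = length(vals), exceedance = exceed,
                 marker_errors = marker_errors,
                 fraction_markers_below = frac_below),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %d voxels evaluated\n", x$n_evaluated))
  cat(sprintf("  mean error %.3f mm, max error %.3f mm\n",
              x$mean_error, x$max_error))
  for (nm in names(x$exceedance))
    cat(sprintf("  fraction %s: %.2f%%\n", nm, 100 * x$exceedance[[nm]]))
  if (!is.null(x$marker_errors)) {
    cat(sprintf("  %d markers, median residual %.3f mm\n",
                length(x$marker_errors), stats::median(x$marker_errors)))
    for (nm in names(x$fraction_markers_below))
      cat(sprintf("  markers %s: %.1f%%\n", nm,
                  100 * x$fraction_markers_below[[nm]]))
  }
  invisible(x)
}

fuse_channels <- function(red_img, green_img) {
  rng <- range(c(red_img$data, green_img$data))
  scale <- if (diff(rng) > 0) diff(rng) else 1
  norm <- function(v) (v - rng[1]) / scale
  k <- ceiling(red_img$dims[3] / 2)
  r <- norm(red_img$data[, , k])
  g <- norm(green_img$data[, , k])
  # transpose + flip rows so +x is right and +y is up in the PNG
  arr <- array(0, c(dim(r)[2], dim(r)[1], 3))
  arr[, , 1] <- t(r)[rev(seq_len(dim(r)[2])), ]
  arr[, , 2] <- t(g)[rev(seq_len(dim(g)[2])), ]
  arr
}

#' Export red/green fusion overlays
#'
#' Writes qualitative before/after fusion images: the target in the red
#' channel and the template (before) or warped template (after) in green,
#' so agreement shows as yellow.  For 3D volumes the central axial slice
#' is exported.
#'
#' @param template,target,warped [volume_image()]s on the same grid
#'   (`warped` may be `NULL` to export only the "before" view).
#' @param path_prefix output prefix; files `<prefix>_before.png` and
#'   `<prefix>_after.png` are written.
#' @return Invisibly, a named list of the written paths with the fusion
#'   arrays attached as attributes `before`/`after`.
#' @export
export_overlay <- function(template, target, warped = NULL,
                           path_prefix = "overlay") {
  stopifnot_volume(template, "template")
  stopifnot_volume(target, "target")
  if (!identical(template$dims, target$dims))
    stop("template and target grids differ")
  before <- fuse_channels(target, template)
  paths <- list(before = paste0(path_prefix, "_before.png"))
  png::writePNG(before, paths$before)
  after <- NULL
  if (!is.null(warped)) {
    stopifnot_volume(warped, "warped")
    after <- fuse_channels(target, warped)
    paths$after <- paste0(path_prefix, "_after.png")
    png::writePNG(after, paths$after)
  }
  out <- paths
  attr(out, "before") <- before
  attr(out, "after") <- after
  invisible(out)
}
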