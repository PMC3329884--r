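#' Pipeline configuration
#'
#' Bundles every tunable of the registration pipeline so a run is fully
#' described by one object; the resolved configuration is echoed into the
#' run log, and identical inputs plus an identical configuration give
#' bit-identical results.
#'
#' @param detection a [detection_config()].
#' @param matching a [match_config()].
#' @param kernel,ridge thin-plate-spline options (see [fit_tps()]).
#' @param weighting,normalize descriptor options (see
#'   [compute_descriptors()]).
#' @param fill out-of-bounds fill for warping (`NULL`: template minimum).
#' @param verbose emit per-stage progress messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            matching = match_config(),
                            kernel = c("r2logr2", "r"), ridge = 0,
                            weighting = c("magnitude", "count"),
                            normalize = FALSE, fill = NULL,
                            verbose = FALSE) {
  structure(list(detection = detection, matching = matching,
                 kernel = match.arg(kernel), ridge = ridge,
                 weighting = match.arg(weighting), normalize = normalize,
                 fill = fill, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full feature-based deformable registration
#'
#' Executes the three stages of the method in order: (1) feature points
#' are detected on both images from local gradient energy; (2) each point
#' is signed with its gradient orientation-histogram descriptor and
#' template/target points are associated by the least-squares ratio test,
#' then pruned by the bidirectional consistency filter; (3) the surviving
#' pairs serve as control points for a thin-plate spline fitted with
#' source = target landmarks and destination = template landmarks, which
#' is densified into a target-to-template displacement field on the target
#' grid and used to backward-warp the template.
#'
#' @param template,target [volume_image()]s of the same dimensionality
#'   (2D with 2D, 3D with 3D).
#' @param config a [pipeline_config()].
#' @param field compute the dense displacement field (and, when `warp` is
#'   `TRUE`, the warped template); turn off to obtain only the model and
#'   matches.
#' @param warp resample the template through the field.
#' @return A list of class `registration_result`: `field`
#'   ([displacement_field()] or `NULL`), `warped` ([volume_image()] or
#'   `NULL`), `model` ([fit_tps()] output), `pairs` (surviving
#'   `match_pairs`), `forward_pairs`, and `log` (per-stage counts and the
#'   echoed configuration).
#' @export
run_registration <- function(template, target, config = pipeline_config(),
                             field = TRUE, warp = TRUE) {
  stopifnot_volume(template, "template")
  stopifnot_volume(target, "target")
  if (template$is2d != target$is2d)
    stop("cannot register a 2D image with a 3D image")
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config")
  say <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))

  t_pts <- detect_feature_points(template, config$detection)
  g_pts <- detect_feature_points(target, config$detection)
  say("detected %d template / %d target feature points", nrow(t_pts), nrow(g_pts))

  d <- if (template$is2d) 2L else 3L
  if (nrow(t_pts) < d + 1L || nrow(g_pts) < d + 1L)
    stop("too few feature points detected; widen the intensity window or lower the saliency threshold")

  t_desc <- compute_descriptors(template, t_pts, weighting = config$weighting,
                                normalize = config$normalize)
  g_desc <- compute_descriptors(target, g_pts, weighting = config$weighting,
                                normalize = config$normalize)

  forward <- match_forward(t_desc, g_desc, config$matching)
  say("%d forward matches (kappa < %g)", nrow(forward),
      config$matching$kappa_threshold)
  pairs <- bidirectional_filter(forward, t_desc, g_desc, config$matching)
  say("%d matches survive the bidirectional filter", nrow(pairs))
  if (nrow(pairs) < d + 1L)
    stop(sprintf(paste("only %d control-point pairs survive but the %dD TPS needs",
                       "at least %d; relax the kappa threshold or lower the",
                       "detection thresholds"),
                 nrow(pairs), d, d + 1L))

  lms <- matches_to_landmarks(pairs)
  model <- fit_tps(lms$target, lms$template, dimensions = d,
                   kernel = config$kernel, ridge = config$ridge)
  dvf <- NULL; warped <- NULL
  if (field) {
    dvf <- tps_to_field(model, target)
    if (warp) warped <- warp_image(template, dvf, fill = config$fill)
  }
  log <- list(detected_template = nrow(t_pts), detected_target = nrow(g_pts),
              forward_matches = nrow(forward), survivors = nrow(pairs),
              surviving_fraction = nrow(pairs) /
                max(1L, min(nrow(t_pts), nrow(g_pts))),
              config = config)
  structure(list(field = dvf, warped = warped, model = model, pairs = pairs,
                 forward_pairs = forward, log = log),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  l <- x$log
  cat("<registration_result>\n")
  cat(sprintf("  feature points: %d template, %d target\n",
              l$detected_template, l$detected_target))
  cat(sprintf("  matches: %d forward, %d after bidirectional filter (%.1f%% of detected)\n",
              l$forward_matches, l$survivors, 100 * l$surviving_fraction))
  if (!is.null(x$field)) {
    mag <- field_magnitude(x$field)
    cat(sprintf("  field: mean |u| %.2f mm, max |u| %.2f mm\n",
                mean(mag), max(mag)))
  }
  invisible(x)
}
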