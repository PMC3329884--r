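#' Standard 2D harmonic-phantom accuracy study
#'
#' A self-contained, fully synthetic analogue of the classic 2D
#' digital-phantom experiment: a 170x170 textured phantom (2 mm pixels,
#' body about 28 x 30 cm) is deformed by the harmonic warp
#' `x' = (1 + b cos(m q)) x` with `b = 0.13`, `m = 2` -- peak displacement
#' `b * 140 mm = 18.2 mm` at the lateral body edge -- and registered back
#' with the full pipeline at default settings.  Accuracy is evaluated
#' against the analytic ground truth over in-body pixels.
#'
#' @param seed RNG seed for the phantom texture.
#' @param b,m harmonic deformation parameters.
#' @param config a [pipeline_config()].
#' @param thresholds error thresholds (mm) for the report.
#' @return A list with the `report` ([summarize_errors()] output), the
#'   registration `result`, the per-pixel `errors` array, the phantom
#'   pieces (`template`, `target`, `truth`, `body`), and
#'   `pre_registration_mean` (mean in-body displacement magnitude, i.e.
#'   the error of doing nothing).
#' @export
harmonic_phantom_study <- function(seed = 1, b = 0.13, m = 2,
                                   config = pipeline_config(),
                                   thresholds = c(2, 10)) {
  spec <- phantom_spec(dims = c(170, 170), spacing = c(2, 2),
                       body_semiaxes = c(140, 150), n_blobs = 700,
                       seed = seed)
  ph <- generate_phantom(spec)
  def <- harmonic_deformation(b = b, m = m,
                              center = spec$body_center[1:2])
  sc <- deform_phantom(ph$image, ph$markers, def, body = ph$body)
  res <- run_registration(ph$image, sc$target, config)
  errors <- error_field(res$field, sc$truth, mask = sc$body)
  report <- summarize_errors(errors, thresholds = thresholds)
  pre <- mean(field_magnitude(sc$truth)[sc$body])
  list(report = report, result = res, errors = errors,
       template = ph$image, target = sc$target, truth = sc$truth,
       body = sc$body, pre_registration_mean = pre)
}

#' Standard 3D marker-phantom accuracy study
#'
#' A desk-scale analogue of a deformable-phantom experiment with rigid
#' spherical markers of known position: a 128^3 textured phantom (2 mm
#' voxels) with embedded spherical markers is deformed by a smooth
#' Gaussian-lobe field with approximately 18 mm peak displacement
#' (mirroring a typical tumour respiratory excursion of 1.8 cm), then
#' registered back with the full pipeline at default settings.  Each
#' marker's residual is the distance between its true template position
#' and the position the fitted transformation assigns to the deformed
#' marker; the headline statistic is the fraction of markers with residual
#' below 2 mm.
#'
#' @param seed RNG seed for the phantom.
#' @param n_markers number of embedded spherical markers.
#' @param peak peak displacement of the main lobe, mm.
#' @param sigma lobe length scale, mm.
#' @param config a [pipeline_config()].
#' @param field also densify the displacement field over the full grid
#'   (needed for voxelwise error maps; marker residuals only need the
#'   fitted model).
#' @param thresholds error thresholds (mm) for the report.
#' @return A list with the `report` (including `marker_errors` and
#'   `fraction_markers_below`), the registration `result`, the phantom
#'   pieces, and the marker sets (`markers_true` on the template,
#'   `markers_deformed` in the target frame, `markers_mapped` through the
#'   registration).
#' @export
marker_phantom_study <- function(seed = 1, n_markers = 24, peak = 18,
                                 sigma = 60, config = pipeline_config(),
                                 field = TRUE, thresholds = c(2, 10)) {
  spec <- phantom_spec(dims = c(128, 128, 128), spacing = c(2, 2, 2),
                       n_blobs = 2500,
                       n_markers = n_markers, marker_radius = 5,
                       marker_contrast = 400, seed = seed)
  ph <- generate_phantom(spec)
  ctr <- spec$body_center
  ax <- spec$body_semiaxes
  # one dominant lobe (superior-posterior, like a diaphragm push) plus two
  # weaker side lobes; amplitudes scaled so the main peak is `peak` mm
  dirs <- rbind(c(0.25, 0.35, 0.90), c(-0.5, 0.4, 0.2), c(0.3, -0.8, -0.4))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  amps <- dirs * c(peak, 0.35 * peak, 0.3 * peak)
  centers <- rbind(ctr + c(0.1, 0.15, 0.35) * ax,
                   ctr + c(-0.4, 0.1, -0.3) * ax,
                   ctr + c(0.3, -0.4, 0.1) * ax)
  def <- lobe_deformation(centers, amps, sigma)
  sc <- deform_phantom(ph$image, ph$markers, def, body = ph$body)
  res <- run_registration(ph$image, sc$target, config, field = field)
  mapped <- evaluate_tps(res$model, landmark_matrix(sc$markers, 3))
  markers_mapped <- landmark_set(mapped, sc$markers$label, dim = 3L)
  errors <- if (field) error_field(res$field, sc$truth, mask = sc$body)
            else NULL
  resid <- sqrt(rowSums((mapped - landmark_matrix(ph$markers, 3))^2))
  report <- summarize_errors(
    if (is.null(errors)) resid else errors,
    markers_true = ph$markers, markers_mapped = markers_mapped,
    thresholds = thresholds)
  list(report = report, result = res, errors = errors,
       template = ph$image, target = sc$target, truth = sc$truth,
       body = sc$body, markers_true = ph$markers,
       markers_deformed = sc$markers, markers_mapped = markers_mapped)
}
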