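#' Thin-plate-spline radial basis function
#'
#' `U(r) = r^2 log(r^2)`, with the limit value 0 at `r = 0`.  This is the
#' classical 2D thin-plate kernel, applied as-is in both 2D and 3D mode
#' (the registration literature this package follows uses it unchanged in
#' 3D); the true 3D biharmonic kernel `U(r) = r` is available via
#' `kernel = "r"`.
#'
#' @param r non-negative distance(s), mm.
#' @param kernel `"r2logr2"` (default) or `"r"`.
#' @return `U(r)`, same shape as `r`.
#' @examples
#' kernel_U(c(0, 1, 2))  # 0, 0, 4*log(4)
#' @export
kernel_U <- function(r, kernel = c("r2logr2", "r")) {
  kernel <- match.arg(kernel)
  if (any(r < 0)) stop("`r` must be non-negative")
  if (kernel == "r") return(r)
  out <- numeric(length(r))
  nz <- r > 0
  out[nz] <- r[nz]^2 * log(r[nz]^2)
  if (!is.null(dim(r))) dim(out) <- dim(r)
  out
}

#' Fit a thin-plate-spline transformation to paired landmarks
#'
#' Builds the standard TPS linear system from `n` control-point pairs: the
#' kernel matrix `K` (`n x n`, zero diagonal, `U(r_ij)` off-diagonal), the
#' affine block `P` (`n x (d+1)`, leading ones), the bordered system
#' `L = [K P; P' O]`, and the right-hand side `Y` holding the destination
#' coordinates over zeros.  Solving `L X = Y` yields, per output component,
#' the kernel weights `W` and affine coefficients `(a1, au, av, aw)`.  The
#' resulting model interpolates every control point exactly (up to solver
#' precision), and the weights satisfy the side conditions `sum(w) = 0` and
#' `sum(w * p) = 0` per coordinate, which kill the kernel's far-field
#' growth and make the affine part the model's behaviour at infinity.
#'
#' Duplicate source points closer than 1e-6 mm are merged (destinations
#' averaged) with a warning, since they make `L` singular.
#'
#' @param source,destination [landmark_set()]s (or `n x d` matrices) with
#'   equal counts `n >= d + 1`; source points must not be collinear (2D) /
#'   coplanar (3D).  For registration use source = target-image landmarks
#'   and destination = template-image landmarks, so the model supports
#'   backward warping.
#' @param dimensions 2 or 3; default taken from the landmark sets.
#' @param kernel see [kernel_U()].
#' @param ridge non-negative regularization added to `K`'s diagonal;
#'   default 0 (exact interpolation).
#' @return An object of class `tps_model` with fields `control_points`
#'   (`n x d`), `weights` (`n x d`), `affine` (`(d+1) x d`, intercept
#'   row first), `d`, `kernel`.
#' @export
fit_tps <- function(source, destination, dimensions = NULL,
                    kernel = c("r2logr2", "r"), ridge = 0) {
  kernel <- match.arg(kernel)
  if (is.null(dimensions)) {
    dimensions <- if (inherits(source, "landmark_set"))
      attr(source, "spdim")
    else if (inherits(destination, "landmark_set"))
      attr(destination, "spdim")
    else ncol(rbind_coerce(source))
  }
  d <- as.integer(dimensions)
  if (!d %in% 2:3) stop("`dimensions` must be 2 or 3")
  src <- if (inherits(source, "landmark_set")) landmark_matrix(source, d)
         else rbind_coerce(source)[, seq_len(d), drop = FALSE]
  dst <- if (inherits(destination, "landmark_set")) landmark_matrix(destination, d)
         else rbind_coerce(destination)[, seq_len(d), drop = FALSE]
  if (nrow(src) != nrow(dst))
    stop(sprintf("source has %d points but destination has %d",
                 nrow(src), nrow(dst)))
  merged <- merge_duplicate_sources(src, dst)
  src <- merged$src; dst <- merged$dst
  n <- nrow(src)
  if (n < d + 1L)
    stop(sprintf("need at least %d control points for %dD, got %d",
                 d + 1L, d, n))
  Pm <- cbind(1, src)
  if (qr(Pm)$rank < d + 1L)
    stop(sprintf("source points are %s; the TPS system is rank-deficient",
                 if (d == 2L) "collinear" else "coplanar"))
  r <- as.matrix(stats::dist(src))
  K <- kernel_U(r, kernel)
  if (ridge > 0) K <- K + diag(ridge, n)
  L <- rbind(cbind(K, Pm), cbind(t(Pm), matrix(0, d + 1L, d + 1L)))
  Y <- rbind(dst, matrix(0, d + 1L, d))
  X <- tryCatch(solve(L, Y), error = function(e)
    stop(sprintf("TPS system is singular (degenerate control-point geometry): %s",
                 conditionMessage(e))))
  structure(list(control_points = src,
                 weights = X[seq_len(n), , drop = FALSE],
                 affine = X[n + seq_len(d + 1L), , drop = FALSE],
                 d = d, kernel = kernel),
            class = "tps_model")
}

merge_duplicate_sources <- function(src, dst, tol = 1e-6) {
  key <- apply(round(src / tol), 1, paste, collapse = ",")
  if (!anyDuplicated(key)) return(list(src = src, dst = dst))
  warning("duplicate source control points merged (destinations averaged)")
  groups <- split(seq_len(nrow(src)), factor(key, levels = unique(key)))
  src2 <- t(vapply(groups, function(g) colMeans(src[g, , drop = FALSE]),
                   numeric(ncol(src))))
  dst2 <- t(vapply(groups, function(g) colMeans(dst[g, , drop = FALSE]),
                   numeric(ncol(dst))))
  list(src = src2, dst = dst2)
}

#' @export
print.tps_model <- function(x, ...) {
  cat(sprintf("<tps_model> %dD, %d control points, kernel %s\n",
              x$d, nrow(x$control_points), x$kernel))
  invisible(x)
}

#' Evaluate a thin-plate-spline model
#'
#' Maps arbitrary points through the fitted transformation: each output
#' component is the affine part plus the weighted sum of kernel terms
#' `w_i U(|p_i - x|)` over the control points.
#'
#' @param model a [tps_model()] from [fit_tps()].
#' @param points `m x d` matrix (or length-d vector, or [landmark_set()])
#'   of physical coordinates, mm.
#' @return `m x d` matrix of mapped coordinates.
#' @export
evaluate_tps <- function(model, points) {
  if (!inherits(model, "tps_model")) stop("`model` must be a tps_model")
  pts <- if (inherits(points, "landmark_set")) landmark_matrix(points, model$d)
         else rbind_coerce(points)
  if (ncol(pts) != model$d)
    stop(sprintf("points have %d columns but the model is %dD",
                 ncol(pts), model$d))
  cpp_tps_eval(pts, model$control_points, model$weights, model$affine,
               if (model$kernel == "r2logr2") 0L else 1L)
}

#' Densify a TPS model into a displacement field
#'
#' Evaluates the model at every voxel centre of `grid` and stores the
#' displacement `f(x) - x`.  With the registration convention (model fitted
#' source = target landmarks, destination = template landmarks) the result
#' is the dense target-to-template field used for backward warping, on the
#' target grid.
#'
#' @param model a [tps_model()].
#' @param grid a [volume_image()] supplying the output grid geometry.
#' @return A [displacement_field()] on `grid`.
#' @export
tps_to_field <- function(model, grid) {
  stopifnot_volume(grid, "grid")
  if ((grid$is2d && model$d != 2L) || (!grid$is2d && model$d != 3L))
    stop("model dimensionality does not match the grid")
  pts <- grid_coordinates(grid)[, seq_len(model$d), drop = FALSE]
  disp <- evaluate_tps(model, pts) - pts
  displacement_field(array(disp, c(grid$dims, model$d)),
                     grid$spacing, grid$origin)
}

grid_coordinates <- function(grid) {
  d <- grid$dims
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Warp an image through a displacement field
#'
#' Backward resampling: the output is defined on the field's (target) grid,
#' and each output voxel takes the template intensity at
#' `voxel centre + displacement`, sampled by linear interpolation.  Sample
#' positions outside the template get `fill` (default: the template
#' minimum, i.e. background).
#'
#' @param template a [volume_image()] to be warped.
#' @param field a [displacement_field()] on the output grid.
#' @param fill out-of-bounds fill value.
#' @return A [volume_image()] on the field's grid.
#' @export
warp_image <- function(template, field, fill = NULL) {
  stopifnot_volume(template, "template")
  if (!inherits(field, "displacement_field"))
    stop("`field` must be a displacement_field")
  if (template$is2d != field$is2d)
    stop("cannot warp a 2D image with a 3D field (or vice versa)")
  if (is.null(fill)) fill <- min(template$data)
  grid <- volume_image(array(0, field$dims), field$spacing, field$origin)
  pts <- grid_coordinates(grid)
  disp <- matrix(field$vectors, ncol = field$d)
  pts[, seq_len(field$d)] <- pts[, seq_len(field$d), drop = FALSE] + disp
  vals <- cpp_sample_linear(template$data, as.integer(template$dims),
                            template$spacing, template$origin, pts, fill)
  volume_image(array(vals, field$dims), field$spacing, field$origin)
}
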