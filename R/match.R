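#' Matching configuration
#'
#' @param kappa_threshold ratio-test threshold in `(0, 1]`: a template
#'   point is associated with its nearest target descriptor only when
#'   `kappa = S1/S2 < kappa_threshold`, where `S1`, `S2` are the two
#'   smallest least-squares descriptor distances.  Default 0.5 ("less than
#'   50%"), which discards ambiguous associations.
#' @param search_radius physical radius (mm): only target points within
#'   this distance of the template point are candidates.  The default of
#'   30 mm is a plausible-displacement prior for respiratory and similar
#'   soft-tissue motion (diaphragm excursion rarely exceeds ~3 cm); it
#'   discards physically impossible associations between distant
#'   lookalike structures, which descriptor distance alone cannot always
#'   separate.  Set `NULL` to search all target points.
#' @return A list of class `match_config`.
#' @export
match_config <- function(kappa_threshold = 0.5, search_radius = 30) {
  if (kappa_threshold <= 0 || kappa_threshold > 1)
    stop("`kappa_threshold` must be in (0, 1]")
  if (!is.null(search_radius) && search_radius <= 0)
    stop("`search_radius` must be > 0 when set")
  structure(list(kappa_threshold = kappa_threshold,
                 search_radius = search_radius),
            class = "match_config")
}

# Lexicographic rank of points by (i, j, k).
lex_order <- function(pts) order(pts$i, pts$j, pts$k)

# One-directional nearest/second-nearest descriptor search with the
# ratio test.  Candidate columns must already be in lexicographic order so
# that "first column wins" tie-breaking is the lexicographic rule.
# Streams over query rows in chunks to bound memory (the full distance
# matrix for 10^4 x 10^4 descriptors would need several GB).
match_rows <- function(A, B, a_xyz, b_xyz, kappa_threshold, radius,
                       chunk = 512L) {
  nt <- nrow(A)
  b2 <- rowSums(B^2)
  best <- integer(nt); S1 <- numeric(nt); S2 <- numeric(nt)
  eligible <- logical(nt)
  for (lo in seq(1L, nt, by = chunk)) {
    hi <- min(lo + chunk - 1L, nt)
    idx <- lo:hi
    D <- outer(rowSums(A[idx, , drop = FALSE]^2), b2, "+") -
      2 * tcrossprod(A[idx, , drop = FALSE], B)
    # the polarization identity loses ~eps*scale to cancellation; snap
    # that noise to exact zero so identical descriptors give S = 0 and
    # the degenerate kappa rules apply deterministically
    D[D < 1e-10 * max(1, max(b2))] <- 0
    if (!is.null(radius)) {
      R2 <- outer(rowSums(a_xyz[idx, , drop = FALSE]^2), rowSums(b_xyz^2), "+") -
        2 * tcrossprod(a_xyz[idx, , drop = FALSE], b_xyz)
      D[R2 > radius^2] <- Inf
    }
    eligible[idx] <- rowSums(is.finite(D)) >= 2L
    m <- length(idx)
    b1 <- max.col(-D, ties.method = "first")
    s1 <- D[cbind(seq_len(m), b1)]
    D[cbind(seq_len(m), b1)] <- Inf
    b2nd <- max.col(-D, ties.method = "first")
    best[idx] <- b1
    S1[idx] <- s1
    S2[idx] <- D[cbind(seq_len(m), b2nd)]
  }
  kappa <- ifelse(S2 == 0, 0, S1 / S2)
  matched <- eligible & kappa < kappa_threshold & is.finite(S1)
  list(best = best, S1 = S1, S2 = S2, kappa = kappa, matched = matched,
       n_skipped = sum(!eligible))
}

match_pair_frame <- function(t_pts, g_pts, t_idx, g_idx, S1, S2, kappa, mode) {
  out <- data.frame(
    template = t_idx, target = g_idx,
    ti = t_pts$i[t_idx], tj = t_pts$j[t_idx], tk = t_pts$k[t_idx],
    tx = t_pts$x[t_idx], ty = t_pts$y[t_idx], tz = t_pts$z[t_idx],
    gi = g_pts$i[g_idx], gj = g_pts$j[g_idx], gk = g_pts$k[g_idx],
    gx = g_pts$x[g_idx], gy = g_pts$y[g_idx], gz = g_pts$z[g_idx],
    S1 = S1, S2 = S2, kappa = kappa)
  class(out) <- c("match_pairs", "data.frame")
  attr(out, "mode") <- mode
  out
}

#' Associate template and target feature points by descriptor distance
#'
#' For every template descriptor the least-squares distance to each
#' eligible target descriptor is computed (all of them, or those within
#' `search_radius`); the two smallest give `S1 <= S2`, and the nearest
#' target point is accepted as the correspondence only when the ratio
#' `kappa = S1/S2` is below the threshold -- otherwise no association is
#' made, avoiding unphysical matches.  Degenerate cases are deterministic:
#' `kappa = 0` when `S2 = 0`, and exact ties for `S1` or `S2` go to the
#' target point with the smaller lexicographic `(i, j, k)`.  Template
#' points with fewer than two eligible candidates are skipped (counted in
#' the `n_skipped` attribute).
#'
#' @param template_desc,target_desc [compute_descriptors()] outputs of the
#'   same mode (both 2D or both 3D); the target set must be non-empty.
#' @param config a [match_config()].
#' @return A data frame of class `match_pairs`, one row per accepted
#'   association: descriptor-set row indices (`template`, `target`), voxel
#'   indices and physical coordinates of both points, and the `S1`, `S2`,
#'   `kappa` diagnostics.
#' @export
match_forward <- function(template_desc, target_desc,
                          config = match_config()) {
  check_desc_pair(template_desc, target_desc)
  t_pts <- attr(template_desc, "points")
  g_pts <- attr(target_desc, "points")
  ord <- lex_order(g_pts)
  res <- match_rows(unclass(template_desc),
                    unclass(target_desc)[ord, , drop = FALSE],
                    as.matrix(t_pts[, c("x", "y", "z")]),
                    as.matrix(g_pts[ord, c("x", "y", "z")]),
                    config$kappa_threshold, config$search_radius)
  if (res$n_skipped > 0)
    message(sprintf("match_forward: %d template point(s) skipped (< 2 eligible candidates)",
                    res$n_skipped))
  sel <- which(res$matched)
  match_pair_frame(t_pts, g_pts, sel, ord[res$best[sel]],
                   res$S1[sel], res$S2[sel], res$kappa[sel],
                   descriptor_mode(template_desc))
}

check_desc_pair <- function(a, b) {
  if (!inherits(a, "sift_descriptors") || !inherits(b, "sift_descriptors"))
    stop("descriptor sets must come from compute_descriptors()")
  if (nrow(a) == 0L) stop("template descriptor set is empty")
  if (nrow(b) == 0L) stop("target descriptor set is empty")
  if (descriptor_mode(a) != descriptor_mode(b))
    stop("cannot match 2D descriptors against 3D descriptors")
  invisible(TRUE)
}

#' Bidirectional consistency filter
#'
#' A correctly associated template point should map back to itself when the
#' matching is run in reverse.  For each forward pair, the reverse matching
#' (target to template, same ratio-test rule) is run for the pair's target
#' point against all template descriptors; the pair survives only when the
#' reverse match exists and returns exactly its template point.  The
#' survivors are a subset of the input and are mutual best matches, which
#' also makes the surviving correspondence one-to-one.
#'
#' @param forward output of [match_forward()] on the same descriptor sets.
#' @param template_desc,target_desc the descriptor sets used for `forward`.
#' @param config a [match_config()]; use the same one as for the forward
#'   pass.
#' @return A `match_pairs` data frame, a subset of `forward`'s rows.
#' @export
bidirectional_filter <- function(forward, template_desc, target_desc,
                                 config = match_config()) {
  if (nrow(forward) == 0L) return(forward)
  check_desc_pair(template_desc, target_desc)
  t_pts <- attr(template_desc, "points")
  g_pts <- attr(target_desc, "points")
  ord <- lex_order(t_pts)
  res <- match_rows(unclass(target_desc),
                    unclass(template_desc)[ord, , drop = FALSE],
                    as.matrix(g_pts[, c("x", "y", "z")]),
                    as.matrix(t_pts[ord, c("x", "y", "z")]),
                    config$kappa_threshold, config$search_radius)
  rev_best <- rep(NA_integer_, nrow(target_desc))
  rev_best[res$matched] <- ord[res$best[res$matched]]
  keep <- !is.na(rev_best[forward$target]) &
          rev_best[forward$target] == forward$template
  out <- forward[keep, , drop = FALSE]
  class(out) <- class(forward)
  attr(out, "mode") <- attr(forward, "mode")
  out
}

#' Convert matched pairs to paired landmark sets
#'
#' The surviving associations become the control points of the thin-plate
#' spline: two index-aligned landmark sets in physical mm, one on the
#' template image and one on the target.
#'
#' @param pairs a non-empty `match_pairs` data frame.
#' @return A list with [landmark_set()]s `template` and `target` in
#'   matching order.
#' @export
matches_to_landmarks <- function(pairs) {
  if (nrow(pairs) == 0L)
    stop(paste("no matched pairs to convert; relax the kappa threshold or",
               "lower the detection thresholds to obtain control points"))
  d <- if (identical(attr(pairs, "mode"), "2d")) 2L else 3L
  labels <- paste0("m", seq_len(nrow(pairs)))
  list(template = landmark_set(as.matrix(pairs[, c("tx", "ty", "tz")]),
                               labels, dim = d),
       target = landmark_set(as.matrix(pairs[, c("gx", "gy", "gz")]),
                             labels, dim = d))
}
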