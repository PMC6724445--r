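#' Convert detector pixel distances to millimetres
#'
#' Pixel distances times the imager pixel spacing give detector-plane mm;
#' dividing further by the magnification `SID/SOD` expresses them at the
#' object (patient) plane, the clinically meaningful scale.
#'
#' @param d_px distances in pixels
#' @param geom a `carm_geometry`
#' @param plane `"object"` (default) or `"detector"`
#' @return distances in mm
#' @export
px_to_mm <- function(d_px, geom, plane = c("object", "detector")) {
  plane <- match.arg(plane)
  d <- d_px * mean(geom$pixel_spacing)
  if (plane == "object") d <- d / magnification(geom)
  d
}

#' Average of distance difference (ADD) between paired markers
#'
#' Mean Euclidean distance over index-paired marker positions, the
#' robustness metric computed on expert-placed corresponding point pairs.
#' Inputs are 2D coordinates in mm (convert pixel coordinates with
#' [px_to_mm()] or supply mm directly).
#'
#' @param markers_proj n x 2 matrix, registered marker positions (mm)
#' @param markers_gt n x 2 matrix, ground-truth marker positions (mm)
#' @return mean distance in mm
#' @export
marker_add <- function(markers_proj, markers_gt) {
  p <- as.matrix(as.data.frame(markers_proj)[, 1:2])
  q <- as.matrix(as.data.frame(markers_gt)[, 1:2])
  if (nrow(p) != nrow(q)) abort("marker counts differ")
  if (nrow(p) == 0L) abort("no markers")
  mean(sqrt(rowSums((p - q)^2)))
}

# exact nearest distance (px) from each point to the set pixels of a mask
nearest_mask_dist <- function(points_px, gt_mask) {
  src <- mask_pixels(gt_mask)
  if (nrow(src) == 0L) abort("ground-truth mask is empty")
  p <- as.matrix(as.data.frame(points_px)[, 1:2])
  if (nrow(p) == 0L) abort("no projected points")
  # exact exhaustive nearest-source search (oracle-grade, not the capped map)
  vapply(seq_len(nrow(p)), function(i) {
    sqrt(min((src[, 1] - p[i, 1])^2 + (src[, 2] - p[i, 2])^2))
  }, numeric(1))
}

#' Centerline error against a ground-truth mask
#'
#' Mean, over the projected 3D centerline points, of the exact distance to
#' the nearest ground-truth centerline pixel (exhaustive search, not the
#' capped distance map), converted to mm.
#'
#' @param points_px n x 2 projected centerline points, pixels
#' @param gt_mask binary ground-truth centerline raster
#' @param geom a `carm_geometry` (for spacing and magnification)
#' @param plane `"object"` (default) or `"detector"`
#' @return mean distance in mm
#' @export
centerline_error <- function(points_px, gt_mask, geom,
                             plane = c("object", "detector")) {
  mean(px_to_mm(nearest_mask_dist(points_px, gt_mask), geom, plane))
}

#' Bifurcation error between projected and ground-truth bifurcation sets
#'
#' Greedy one-to-one matching by increasing distance (no pairing ids exist
#' for bifurcations), then the mean matched distance. Inputs in mm.
#'
#' @param bif_proj n x 2 projected bifurcation points (mm)
#' @param bif_gt m x 2 ground-truth bifurcation points (mm), `m >= 1`
#' @return mean matched distance in mm
#' @export
bifurcation_error <- function(bif_proj, bif_gt) {
  p <- as.matrix(as.data.frame(bif_proj)[, 1:2])
  q <- as.matrix(as.data.frame(bif_gt)[, 1:2])
  if (nrow(p) == 0L) abort("no projected bifurcations")
  if (nrow(q) == 0L) abort("no ground-truth bifurcations")
  d <- outer(seq_len(nrow(p)), seq_len(nrow(q)),
             Vectorize(function(i, j) sqrt(sum((p[i, ] - q[j, ])^2))))
  n_match <- min(nrow(p), nrow(q))
  matched <- numeric(n_match)
  for (k in seq_len(n_match)) {
    ij <- arrayInd(which.min(d), dim(d))
    matched[k] <- d[ij]
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  mean(matched)
}

#' In-plane reprojection error between two poses
#'
#' Projects the same 3D points under a recovered and a reference
#' (ground-truth) pose and returns the mean 2D distance in mm — the
#' recovery metric used on synthetic cases where the true pose is known.
#'
#' @param points3d n x 3 matrix, patient mm
#' @param geom a `carm_geometry`
#' @param pose a `rigid_transform` (recovered)
#' @param pose_ref a `rigid_transform` (ground truth)
#' @param center rotation center (tree centroid)
#' @param plane `"object"` (default) or `"detector"`
#' @return mean reprojection distance in mm
#' @export
reprojection_error <- function(points3d, geom, pose, pose_ref, center = NULL,
                               plane = c("object", "detector")) {
  points3d <- as.matrix(points3d)
  if (is.null(center)) center <- colMeans(points3d)
  a <- project_points(points3d, geom, pose, center)
  b <- project_points(points3d, geom, pose_ref, center)
  mean(px_to_mm(sqrt((a$x - b$x)^2 + (a$y - b$y)^2), geom, plane))
}

#' Evaluate a registration result against ground truth
#'
#' Computes the three accuracy metrics (centerline, marker, bifurcation
#' error) of a registered case in one call.
#'
#' @param result a `registration_result`
#' @param tree the registered `vessel_tree`
#' @param gt_mask ground-truth 2D centerline mask
#' @param gt_pose optional ground-truth `rigid_transform`; enables marker
#'   and bifurcation metrics (ground-truth 2D positions are the projections
#'   under this pose)
#' @param plane `"object"` or `"detector"`
#' @return one-row tibble with `centerline_mm` and, when `gt_pose` is
#'   given, `marker_mm`, `bifurcation_mm` and `reprojection_mm`
#' @export
evaluate_registration <- function(result, tree, gt_mask, gt_pose = NULL,
                                  plane = c("object", "detector")) {
  plane <- match.arg(plane)
  geom <- result$geom
  pts <- tree_points(tree)
  out <- tibble(centerline_mm = centerline_error(
    cbind(result$projected$x, result$projected$y), gt_mask, geom, plane))
  if (!is.null(gt_pose)) {
    proj_mm <- function(p3, pose) {
      pr <- project_points(p3, geom, pose, result$center)
      cbind(px_to_mm(pr$x, geom, plane), px_to_mm(pr$y, geom, plane))
    }
    if (nrow(tree$markers) > 0L) {
      mk <- pts[tree$markers$point, , drop = FALSE]
      out$marker_mm <- marker_add(proj_mm(mk, result$pose),
                                  proj_mm(mk, gt_pose))
    }
    bif <- extract_bifurcations(tree)
    if (nrow(bif) > 0L) {
      bif <- as.matrix(bif)
      out$bifurcation_mm <- bifurcation_error(proj_mm(bif, result$pose),
                                              proj_mm(bif, gt_pose))
    }
    out$reprojection_mm <- reprojection_error(pts, geom, result$pose,
                                              gt_pose, result$center, plane)
  }
  out
}
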