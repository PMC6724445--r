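#' Construct C-arm acquisition geometry
#'
#' Holds the five acquisition parameters carried in angiography DICOM
#' headers plus image/principal-point information, from which the pinhole
#' projection is built. Angle conventions: primary angle rotates about the
#' patient head-foot axis (RAO negative / LAO positive), secondary about the
#' patient left-right axis (caudal negative / cranial positive). At zero
#' angles the source sits anterior to the patient looking posteriorly
#' (PA-like geometry).
#'
#' @param primary_angle positioner primary angle, degrees
#' @param secondary_angle positioner secondary angle, degrees
#' @param sid distance source to detector, mm (a signed value is stored as
#'   its absolute value with a warning; a signed SID is physically
#'   meaningless)
#' @param sod distance source to patient (isocenter), mm; must satisfy
#'   `sid > sod > 0`
#' @param pixel_spacing imager pixel spacing, mm/px; scalar or `(row, col)`
#' @param image_size `(rows, cols)`, default `c(512, 512)`
#' @param principal_point `(px, py)` pixels; defaults to the image center
#' @return object of class `carm_geometry`
#' @export
carm_geometry <- function(primary_angle, secondary_angle, sid, sod,
                          pixel_spacing, image_size = c(512L, 512L),
                          principal_point = NULL) {
  if (!all(is.finite(c(primary_angle, secondary_angle, sid, sod, pixel_spacing)))) {
    abort("geometry parameters must be finite")
  }
  if (sid < 0) {
    warn(sprintf("negative SID %g taken as %g mm", sid, abs(sid)))
    sid <- abs(sid)
  }
  if (any(pixel_spacing <= 0)) abort("pixel_spacing must be > 0")
  if (!(sid > sod && sod > 0)) abort("geometry requires sid > sod > 0")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (is.null(principal_point)) {
    principal_point <- c((image_size[2] - 1) / 2, (image_size[1] - 1) / 2)
  }
  structure(list(primary_angle = primary_angle, secondary_angle = secondary_angle,
                 sid = sid, sod = sod, pixel_spacing = as.numeric(pixel_spacing),
                 image_size = as.integer(image_size),
                 principal_point = as.numeric(principal_point)),
            class = "carm_geometry")
}

#' @export
print.carm_geometry <- function(x, ...) {
  cat(sprintf(
    "<carm_geometry> primary %.4g deg, secondary %.4g deg, SID %.4g mm, SOD %.4g mm\n",
    x$primary_angle, x$secondary_angle, x$sid, x$sod))
  cat(sprintf("  spacing %s mm/px, image %dx%d, principal point (%.4g, %.4g)\n",
              paste(signif(x$pixel_spacing, 4), collapse = "x"),
              x$image_size[1], x$image_size[2],
              x$principal_point[1], x$principal_point[2]))
  invisible(x)
}

#' Geometric magnification at the isocenter plane
#' @param geom a `carm_geometry`
#' @return sid / sod (dimensionless)
#' @export
magnification <- function(geom) geom$sid / geom$sod

rot_x <- function(deg) {
  a <- deg * pi / 180; c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE)
}
rot_y <- function(deg) {
  a <- deg * pi / 180; c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE)
}
rot_z <- function(deg) {
  a <- deg * pi / 180; c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Intrinsic camera matrix of a C-arm geometry
#'
#' `K = [[f mx, 0, px], [0, f my, py], [0, 0, 1]]` with focal length
#' `f = SID` (mm) and `m = 1 / pixel_spacing` (px/mm), so the detector-plane
#' magnification `SID/SOD` is encoded entirely by `f` and no separate
#' magnification correction is applied to the pixel spacing.
#'
#' @param geom a `carm_geometry`
#' @return 3 x 3 numeric matrix
#' @export
intrinsic_matrix <- function(geom) {
  m <- 1 / geom$pixel_spacing           # (row, col) -> (my, mx)
  matrix(c(geom$sid * m[2], 0, geom$principal_point[1],
           0, geom$sid * m[1], geom$principal_point[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Extrinsic rotation and translation of a C-arm geometry
#'
#' Maps patient coordinates (x: patient left, y: posterior, z: head,
#' isocenter at the origin) into a camera frame whose +z axis points from
#' the X-ray source toward the detector. The camera sits at distance SOD
#' from the isocenter: `t = (0, 0, sod)`. Composition is
#' `R = R_base %*% R_secondary %*% R_primary` with the primary rotation
#' about the patient z (head-foot) axis and the secondary about the patient
#' x (left-right) axis; `R_base` realizes the zero-angle PA-like view
#' (source anterior).
#'
#' @param geom a `carm_geometry`
#' @return list with `R` (3 x 3 rotation) and `t` (length-3 mm vector)
#' @export
extrinsic_from_angles <- function(geom) {
  r_base <- matrix(c(1, 0, 0,
                     0, 0, -1,
                     0, 1, 0), 3, 3, byrow = TRUE)
  R <- r_base %*% rot_x(geom$secondary_angle) %*% rot_z(geom$primary_angle)
  list(R = R, t = c(0, 0, geom$sod))
}

#' Construct a rigid pose (6-parameter transform)
#'
#' Translation in patient-space mm and rotations in degrees about the
#' patient axes through a rotation center (by default the centerline-tree
#' centroid, supplied at application time).
#'
#' @param t `(Tx, Ty, Tz)` mm
#' @param r `(Rx, Ry, Rz)` degrees
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(t = c(0, 0, 0), r = c(0, 0, 0)) {
  stopifnot(length(t) == 3L, length(r) == 3L, all(is.finite(c(t, r))))
  structure(list(t = as.numeric(t), r = as.numeric(r)), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> T = (%.3g, %.3g, %.3g) mm, R = (%.3g, %.3g, %.3g) deg\n",
              x$t[1], x$t[2], x$t[3], x$r[1], x$r[2], x$r[3]))
  invisible(x)
}

pose_rotation <- function(pose) rot_z(pose$r[3]) %*% rot_y(pose$r[2]) %*% rot_x(pose$r[1])

#' Apply a rigid pose to 3D points
#'
#' `P' = Rz Ry Rx (P - center) + center + t`: rotation about `center`
#' followed by translation. Exactly rigid (pairwise distances preserved).
#'
#' @param points3d n x 3 matrix, mm
#' @param pose a `rigid_transform`
#' @param center length-3 rotation center, mm; default the centroid of
#'   `points3d`
#' @return n x 3 matrix
#' @export
apply_rigid <- function(points3d, pose, center = NULL) {
  points3d <- as.matrix(points3d)
  if (is.null(center)) center <- colMeans(points3d)
  R <- pose_rotation(pose)
  shifted <- sweep(points3d, 2, center)
  out <- shifted %*% t(R)
  sweep(out, 2, center + pose$t, FUN = "+")
}

#' Invert a rigid pose about a fixed center
#' @param pose a `rigid_transform`
#' @param center rotation center used when the pose is applied
#' @return the `rigid_transform` that undoes `pose` about the same center
#' @export
invert_rigid <- function(pose, center = c(0, 0, 0)) {
  R <- pose_rotation(pose)
  # inverse map: P = R^T (P' - center - t) + center; recover angles of R^T
  Rt <- t(R)
  ry <- asin(pmin(1, pmax(-1, -Rt[3, 1])))
  rx <- atan2(Rt[3, 2], Rt[3, 3])
  rz <- atan2(Rt[2, 1], Rt[1, 1])
  r_inv <- c(rx, ry, rz) * 180 / pi
  t_inv <- as.numeric(Rt %*% (-pose$t))
  rigid_transform(t = t_inv, r = r_inv)
}

#' Project 3D points through a C-arm geometry onto the detector
#'
#' Applies the rigid pose, maps into the camera frame by the extrinsics and
#' dehomogenizes through the intrinsic matrix:
#' `(x, y) ~ K [R | t] pose(P)`. Points at or behind the source plane are an
#' error.
#'
#' @param points3d n x 3 matrix, patient mm
#' @param geom a `carm_geometry`
#' @param pose a `rigid_transform` (default identity)
#' @param center rotation center for the pose; default centroid of
#'   `points3d`
#' @return tibble with columns `x`, `y` (pixels) and `depth` (camera z, mm)
#' @export
project_points <- function(points3d, geom, pose = rigid_transform(), center = NULL) {
  points3d <- as.matrix(points3d)
  if (nrow(points3d) == 0L) abort("no points to project")
  moved <- apply_rigid(points3d, pose, center)
  ext <- extrinsic_from_angles(geom)
  cam <- moved %*% t(ext$R)
  cam <- sweep(cam, 2, ext$t, FUN = "+")
  if (any(cam[, 3] <= 1e-6)) abort("point behind source")
  K <- intrinsic_matrix(geom)
  u <- cam %*% t(K)
  tibble(x = u[, 1] / u[, 3], y = u[, 2] / u[, 3], depth = cam[, 3])
}
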