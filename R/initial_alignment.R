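#' Axis-aligned bounding box of 2D points
#' @param points2d n x 2 matrix or data frame of `(x, y)` coordinates
#' @return named numeric vector `(xmin, ymin, xmax, ymax)`
#' @export
bounding_box <- function(points2d) {
  points2d <- as.matrix(as.data.frame(points2d)[, 1:2])
  if (nrow(points2d) == 0L) abort("empty point set")
  c(xmin = min(points2d[, 1]), ymin = min(points2d[, 2]),
    xmax = max(points2d[, 1]), ymax = max(points2d[, 2]))
}

#' Expand a bounding box by a margin
#'
#' Moves every side of the box outward by `e` pixels; the margin absorbs
#' residual cardiac deformation and geometric mismatch between the two
#' centerlines. When `image_size` is supplied the expanded box is clipped
#' to the image.
#'
#' @param box `(xmin, ymin, xmax, ymax)`
#' @param e margin in pixels, `>= 0` (default 10)
#' @param image_size optional `(rows, cols)` for clipping
#' @return expanded box
#' @export
expand_box <- function(box, e = 10, image_size = NULL) {
  if (e < 0) abort("margin must be >= 0")
  out <- c(xmin = box[["xmin"]] - e, ymin = box[["ymin"]] - e,
           xmax = box[["xmax"]] + e, ymax = box[["ymax"]] + e)
  if (!is.null(image_size)) {
    out["xmin"] <- max(out[["xmin"]], 0)
    out["ymin"] <- max(out[["ymin"]], 0)
    out["xmax"] <- min(out[["xmax"]], image_size[2] - 1)
    out["ymax"] <- min(out[["ymax"]], image_size[1] - 1)
  }
  out
}

box_center <- function(box) c((box[["xmin"]] + box[["xmax"]]) / 2,
                              (box[["ymin"]] + box[["ymax"]]) / 2)
box_diag <- function(box) sqrt((box[["xmax"]] - box[["xmin"]])^2 +
                               (box[["ymax"]] - box[["ymin"]])^2)

#' Initial translation estimate from bounding-box matching
#'
#' The C-arm metadata fixes rotation and magnification but carries no
#' patient translation, so the missing translation is estimated by matching
#' the bounding boxes of the projected 3D and the 2D centerlines: in-plane,
#' the pixel offset between box centers is converted to mm at the object
#' plane (divide by `SID/SOD` magnification, then by pixel spacing in px/mm)
#' and mapped back into patient axes through the extrinsic rotation; in
#' depth, the ratio of box diagonals gives a shift along the viewing axis
#' via the perspective relation (projected scale proportional to
#' `SID / camera-z`).
#'
#' @param box3d_proj bounding box of the projected 3D centerline (pixels)
#' @param box2d bounding box of the 2D centerline (pixels)
#' @param geom a `carm_geometry`
#' @param estimate_depth also estimate the depth shift from the diagonal
#'   ratio (default `TRUE`)
#' @return a translation-only `rigid_transform` (patient mm)
#' @export
initial_translation <- function(box3d_proj, box2d, geom, estimate_depth = TRUE) {
  d_px <- box_center(box2d) - box_center(box3d_proj)
  # px -> mm at the object plane: spacing (mm/px at detector) / magnification
  mag <- magnification(geom)
  dx <- d_px[1] * geom$pixel_spacing[2] / mag
  dy <- d_px[2] * geom$pixel_spacing[1] / mag
  dz <- 0
  diag3 <- box_diag(box3d_proj); diag2 <- box_diag(box2d)
  if (estimate_depth) {
    if (diag3 < .Machine$double.eps || diag2 < .Machine$double.eps) {
      warn("degenerate bounding box; depth left at 0")
    } else {
      # scale ratio s = diag2/diag3 needs camera z' = z * diag3/diag2
      dz <- geom$sod * (diag3 / diag2 - 1)
    }
  }
  ext <- extrinsic_from_angles(geom)
  t_patient <- as.numeric(t(ext$R) %*% c(dx, dy, dz))
  rigid_transform(t = t_patient, r = c(0, 0, 0))
}
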