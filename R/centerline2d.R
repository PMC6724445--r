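#' Construct a 2D vessel centerline
#'
#' A `centerline2d` holds the intraoperative vessel centerline as a binary
#' raster mask and/or as ordered pixel polylines. When constructed from
#' polylines the mask is rasterized (8-connected); when constructed from a
#' mask the polylines are absent unless traced separately (tracing is not
#' needed for registration — only the mask feeds the distance map).
#'
#' @param mask binary matrix (`[row, col]`, nonzero = centerline), or `NULL`
#' @param polylines list of n x 2 matrices of `(x, y)` pixel coordinates
#'   (x = column, y = row, 0-based), or `NULL`
#' @param pixel_spacing mm per pixel at the detector (scalar or length-2
#'   `(row, col)`)
#' @param image_size `(rows, cols)`; required when only polylines are given
#' @return an object of class `centerline2d`
#' @export
centerline2d <- function(mask = NULL, polylines = NULL, pixel_spacing = NA_real_,
                         image_size = NULL) {
  if (is.null(mask) && is.null(polylines)) abort("supply a mask or polylines")
  if (is.null(mask)) {
    if (is.null(image_size)) abort("image_size required when constructing from polylines")
    mask <- rasterize_polyline(polylines, image_size)
  } else {
    mask <- (mask != 0) * 1L
    storage.mode(mask) <- "integer"
    image_size <- dim(mask)
    if (!is.null(polylines) &&
        !identical(rasterize_polyline(polylines, image_size), mask)) {
      abort("mask and polylines rasterize to different pixel sets")
    }
  }
  structure(list(mask = mask, polylines = polylines,
                 pixel_spacing = pixel_spacing,
                 image_size = as.integer(image_size)),
            class = "centerline2d")
}

#' @export
print.centerline2d <- function(x, ...) {
  cat(sprintf("<centerline2d> %dx%d px, %d centerline pixels, spacing %s mm/px\n",
              x$image_size[1], x$image_size[2], sum(x$mask),
              paste(signif(x$pixel_spacing, 4), collapse = "x")))
  invisible(x)
}

#' Pixel coordinates set in a mask
#' @param mask binary matrix
#' @return m x 2 matrix of `(x, y)` 0-based pixel coordinates
#' @export
mask_pixels <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

# 8-connected DDA trace between two integer pixels (inclusive)
trace_segment <- function(p0, p1) {
  n <- max(abs(p1 - p0)) + 1L
  if (n == 1L) return(matrix(p0, ncol = 2))
  cbind(round(seq(p0[1], p1[1], length.out = n)),
        round(seq(p0[2], p1[2], length.out = n)))
}

#' Rasterize pixel polylines into a binary mask
#'
#' Draws each ordered chain of `(x, y)` pixel coordinates into a binary
#' raster by 8-connected (Bresenham-style) line tracing. Vertex coordinates
#' may be fractional; they are rounded to the nearest pixel center.
#'
#' @param polylines one n x 2 matrix or a list of them, `(x, y)` 0-based
#' @param image_size `(rows, cols)`
#' @return integer matrix of 0/1, `dim = image_size`
#' @export
rasterize_polyline <- function(polylines, image_size) {
  if (is.matrix(polylines)) polylines <- list(polylines)
  rows <- image_size[1]; cols <- image_size[2]
  mask <- matrix(0L, rows, cols)
  for (k in seq_along(polylines)) {
    pl <- round(polylines[[k]])
    bad <- which(pl[, 1] < 0 | pl[, 1] > cols - 1 | pl[, 2] < 0 | pl[, 2] > rows - 1)
    if (length(bad) > 0L) {
      abort(sprintf("polyline %d vertex %d (%g, %g) outside %dx%d image",
                    k, bad[1], pl[bad[1], 1], pl[bad[1], 2], rows, cols))
    }
    if (nrow(pl) == 1L) {
      mask[pl[1, 2] + 1L, pl[1, 1] + 1L] <- 1L
      next
    }
    for (i in seq_len(nrow(pl) - 1L)) {
      px <- trace_segment(pl[i, ], pl[i + 1L, ])
      mask[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- 1L
    }
  }
  mask
}
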