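#' Build a capped local distance map from a centerline mask
#'
#' Propagates distances from every centerline pixel over the 8-neighbor
#' pixel graph with chamfer steps 1 (edge) and sqrt(2) (diagonal), by
#' repeated forward/backward raster sweeps iterated to a fixed point (the
#' result is therefore independent of scan order). Distances are capped at
#' `d_max`: every pixel farther than the cap — where the map is irrelevant
#' for a bounded pose search — holds exactly `d_max`. The chamfer
#' approximation overestimates the true Euclidean distance by at most about
#' 8.2 percent.
#'
#' @param mask binary matrix (nonzero = centerline) or a `centerline2d`
#' @param d_max cap, in the same unit as the map (pixels); `> 0`
#' @return object of class `local_distance_map` with fields `grid`
#'   (distance per pixel), `d_max`, `unit` (`"px"`) and `source_mask`
#' @export
build_local_distance_map <- function(mask, d_max) {
  if (inherits(mask, "centerline2d")) mask <- mask$mask
  if (!is.finite(d_max) || d_max <= 0) abort("d_max must be > 0")
  m <- (mask != 0) * 1L
  storage.mode(m) <- "integer"
  if (sum(m) == 0L) abort("no centerline pixels")
  grid <- chamfer_sweep(m, d_max)
  structure(list(grid = grid, d_max = d_max, unit = "px", source_mask = m),
            class = "local_distance_map")
}

#' @export
print.local_distance_map <- function(x, ...) {
  cat(sprintf("<local_distance_map> %dx%d px, d_max = %g %s, %d source pixels\n",
              nrow(x$grid), ncol(x$grid), x$d_max, x$unit, sum(x$source_mask)))
  invisible(x)
}

#' Query a local distance map at continuous pixel coordinates
#'
#' Nearest-pixel lookup by default; bilinear interpolation gives a smoother
#' objective landscape for the optimizer. Points outside the image return
#' `d_max`.
#'
#' @param map a `local_distance_map`
#' @param points n x 2 matrix or data frame of `(x, y)` pixel coordinates
#'   (x = column, y = row, 0-based, origin at the top-left pixel center)
#' @param mode `"nearest"` or `"bilinear"`
#' @return numeric vector of distances in the map's unit
#' @export
ldm_query <- function(map, points, mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  points <- as.matrix(as.data.frame(points)[, 1:2])
  nr <- nrow(map$grid); nc <- ncol(map$grid)
  x <- points[, 1]; y <- points[, 2]
  out <- rep(map$d_max, nrow(points))
  if (mode == "nearest") {
    xi <- round(x); yi <- round(y)
    inside <- xi >= 0 & xi <= nc - 1 & yi >= 0 & yi <= nr - 1
    out[inside] <- map$grid[cbind(yi[inside] + 1, xi[inside] + 1)]
  } else {
    inside <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
    if (any(inside)) {
      xs <- x[inside]; ys <- y[inside]
      x0 <- pmin(floor(xs), nc - 2); y0 <- pmin(floor(ys), nr - 2)
      fx <- xs - x0; fy <- ys - y0
      g <- map$grid
      v00 <- g[cbind(y0 + 1, x0 + 1)]; v01 <- g[cbind(y0 + 1, x0 + 2)]
      v10 <- g[cbind(y0 + 2, x0 + 1)]; v11 <- g[cbind(y0 + 2, x0 + 2)]
      out[inside] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                     fy * ((1 - fx) * v10 + fx * v11)
    }
  }
  out
}

#' Write a distance map as a plain-text grid (TSV)
#'
#' Debug export mirroring a float raster dump; one row per image row.
#'
#' @param map a `local_distance_map`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_distance_map <- function(map, path) {
  utils::write.table(map$grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
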