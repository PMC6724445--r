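#' Write a vessel tree to the package JSON schema
#'
#' Schema: `{side, branches: [{id, parent, attach_index, class,
#' main_label, points: [[x,y,z], ...], segment_labels}], markers:
#' [{branch, index, id}]}`. `attach_index` and marker `index` are 1-based
#' positions within the referenced branch's own point list.
#'
#' @param tree a `vessel_tree`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tree_json <- function(tree, path) {
  branches <- lapply(seq_len(nrow(tree$branches)), function(i) {
    bid <- tree$branches$id[i]
    rows <- branch_rows(tree, bid)
    b <- list(id = bid, parent = tree$branches$parent[i],
              class = tree$branches$class[i],
              main_label = tree$branches$main_label[i],
              points = unname(as.matrix(tree$points[rows, c("x", "y", "z")])))
    if (!is.na(tree$branches$parent[i])) {
      parent_rows <- branch_rows(tree, tree$branches$parent[i])
      b$attach_index <- match(tree$branches$attach[i], parent_rows)
    }
    seg <- tree$points$segment[rows]
    if (!anyNA(seg)) b$segment_labels <- seg
    if (!all(is.na(tree$points$alpha[rows]))) b$alpha <- tree$points$alpha[rows]
    if (!is.na(tree$branches$active[i])) b$active <- tree$branches$active[i]
    b
  })
  markers <- NULL
  if (nrow(tree$markers) > 0L) {
    markers <- lapply(seq_len(nrow(tree$markers)), function(k) {
      gidx <- tree$markers$point[k]
      bid <- tree$points$branch[gidx]
      list(branch = bid, index = match(gidx, branch_rows(tree, bid)),
           id = tree$markers$id[k])
    })
  }
  jsonlite::write_json(list(side = tree$side, branches = branches,
                            markers = markers),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a vessel tree from the package JSON schema
#' @param path JSON file written by [write_tree_json()] or following its
#'   schema
#' @return a `vessel_tree`
#' @export
read_tree_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  blocks <- list(); binfo <- list()
  for (b in j$branches) {
    pts <- if (is.matrix(b$points)) b$points else
      matrix(unlist(b$points), ncol = 3, byrow = TRUE)
    blocks[[b$id]] <- tibble(
      x = pts[, 1], y = pts[, 2], z = pts[, 3], branch = b$id,
      segment = if (!is.null(b$segment_labels)) unlist(b$segment_labels) else NA_character_,
      alpha = if (!is.null(b$alpha)) unlist(b$alpha) else NA_real_)
    binfo[[b$id]] <- tibble(
      id = b$id, parent = b$parent %||% NA_character_,
      attach_local = b$attach_index %||% NA_integer_,
      class = b$class, main_label = b$main_label %||% NA_character_,
      active = b$active %||% NA)
  }
  points <- dplyr::bind_rows(blocks)
  branches <- dplyr::bind_rows(binfo)
  offsets <- c(0, cumsum(vapply(blocks, nrow, integer(1))))
  names(offsets) <- c(names(blocks), "_end")
  branches$attach <- ifelse(
    is.na(branches$attach_local), NA_integer_,
    as.integer(offsets[branches$parent] + branches$attach_local))
  branches$attach_local <- NULL
  markers <- NULL
  if (length(j$markers) > 0L) {
    markers <- dplyr::bind_rows(lapply(j$markers, function(m) {
      tibble(point = as.integer(offsets[m$branch] + m$index), id = m$id)
    }))
  }
  vessel_tree(points, branches, j$side, markers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read C-arm geometry from a sidecar JSON of DICOM keywords
#'
#' Reads the five acquisition parameters by DICOM keyword from a JSON
#' sidecar: `PositionerPrimaryAngle`, `PositionerSecondaryAngle`,
#' `ImagerPixelSpacing`, `DistanceSourceToDetector`,
#' `DistanceSourceToPatient` (keywords are authoritative; published tag
#' numbers for the positioner angles are inconsistent across sources).
#' Optional keys: `Rows`, `Columns`, `PrincipalPoint`. A signed
#' source-to-detector distance is stored as its absolute value with a
#' warning; a missing principal point defaults to the image center.
#'
#' @param path JSON file
#' @return a `carm_geometry`
#' @export
read_geometry <- function(path) {
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) {
    abort(paste("raw DICOM input is not supported; export the header to a",
                "JSON sidecar with the five acquisition keywords"))
  }
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("PositionerPrimaryAngle", "PositionerSecondaryAngle",
            "ImagerPixelSpacing", "DistanceSourceToDetector",
            "DistanceSourceToPatient")
  missing <- setdiff(need, names(j))
  if (length(missing) > 0L) {
    abort(sprintf("missing mandatory geometry keyword(s): %s",
                  paste(missing, collapse = ", ")))
  }
  image_size <- c(j$Rows %||% 512L, j$Columns %||% 512L)
  carm_geometry(primary_angle = j$PositionerPrimaryAngle,
                secondary_angle = j$PositionerSecondaryAngle,
                sid = j$DistanceSourceToDetector,
                sod = j$DistanceSourceToPatient,
                pixel_spacing = j$ImagerPixelSpacing,
                image_size = image_size,
                principal_point = j$PrincipalPoint %||% NULL)
}

#' Write C-arm geometry as a sidecar JSON
#' @param geom a `carm_geometry`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(
    list(PositionerPrimaryAngle = geom$primary_angle,
         PositionerSecondaryAngle = geom$secondary_angle,
         ImagerPixelSpacing = geom$pixel_spacing,
         DistanceSourceToDetector = geom$sid,
         DistanceSourceToPatient = geom$sod,
         Rows = geom$image_size[1], Columns = geom$image_size[2],
         PrincipalPoint = geom$principal_point),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary centerline mask from a PNG file
#' @param path PNG file; any nonzero pixel is centerline
#' @return integer 0/1 matrix
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  (img > 0) * 1L
}

#' Write a binary mask as a PNG file
#' @param mask binary matrix
#' @param path output file
#' @return `path`, invisibly
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Read an ECG trace from CSV
#' @param path CSV with columns `time`, `value` (uniform sampling assumed)
#' @param frame_times optional XA frame timestamps (s)
#' @return an `ecg_trace`
#' @export
read_ecg_csv <- function(path, frame_times = numeric()) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time", "value") %in% names(d)))
  fs <- 1 / mean(diff(d$time))
  ecg_trace(d$value, fs, frame_times)
}

#' Write an ECG trace to CSV
#' @param trace an `ecg_trace`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ecg_csv <- function(trace, path) {
  t <- seq_along(trace$samples) / trace$fs
  utils::write.csv(data.frame(time = t, value = trace$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Complete documented default set; a YAML config file ([read_config()])
#' overrides any subset, and CLI flags override the file.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    importance = list(alpha_min = 0.1, alpha_max = 1.0, decay_per_mm = 0.02,
                      reference_counts = list(proximal = 2, mid = 2, distal = 1)),
    initial = list(margin_px = 10, estimate_depth = TRUE),
    registration = list(th_R = 12, d_max = 13, query_mode = "bilinear",
                        par_tol = 1e-3, fn_tol = 1e-4, max_iter = 200,
                        restarts = 0),
    cardiac = list(min_rr = 0.3, tol = 0.05),
    resample_step = 0.5,
    evaluation = list(plane = "object")
  )
}

#' Read a YAML configuration file over the defaults
#' @param path YAML file, or `NULL` for pure defaults
#' @return nested named list (defaults overridden by the file)
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  cfg
}

config_to_registration <- function(cfg) {
  registration_config(th_R = cfg$registration$th_R,
                      d_max = cfg$registration$d_max,
                      query_mode = cfg$registration$query_mode,
                      par_tol = cfg$registration$par_tol,
                      fn_tol = cfg$registration$fn_tol,
                      max_iter = cfg$registration$max_iter,
                      restarts = cfg$registration$restarts,
                      estimate_depth = cfg$initial$estimate_depth,
                      margin_px = cfg$initial$margin_px)
}
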