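# run code under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# smooth 3D curve of a target arc length: random-walk control points with
# bounded turning, cubic-spline interpolated, then rescaled to the length
smooth_curve3d <- function(start, direction, length_mm, turn_sd_deg = 18,
                           n_ctrl = 7, n_dense = 200) {
  dir <- direction / sqrt(sum(direction^2))
  step <- length_mm / (n_ctrl - 1)
  ctrl <- matrix(0, n_ctrl, 3)
  ctrl[1, ] <- start
  for (i in 2:n_ctrl) {
    # rotate the running direction by a random small turn about a random axis
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- rnorm(1, 0, turn_sd_deg) * pi / 180
    dir <- dir * cos(ang) + pracma_cross(axis, dir) * sin(ang) +
      axis * sum(axis * dir) * (1 - cos(ang))
    dir <- dir / sqrt(sum(dir^2))
    ctrl[i, ] <- ctrl[i - 1, ] + dir * step
  }
  u <- seq(0, 1, length.out = n_ctrl)
  uu <- seq(0, 1, length.out = n_dense)
  dense <- vapply(1:3, function(j) spline(u, ctrl[, j], xout = uu)$y,
                  numeric(n_dense))
  s <- cum_arclength(dense)
  scale <- length_mm / s[length(s)]
  sweep(dense, 2, dense[1, ]) * scale + matrix(start, n_dense, 3, byrow = TRUE)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a parametric coronary-like 3D centerline tree
#'
#' Builds one smooth main branch (two for the left side: LAD with an LCX
#' splitting off near the root, mimicking the left-main bifurcation),
#' labels its points proximal/mid/distal by arc-length thirds, attaches
#' sub-branches at random arc positions, places markers on the main branch,
#' centers the tree on the isocenter and resamples everything at
#' `resample_step`. Deterministic per seed.
#'
#' @param side `"LCA"` or `"RCA"`
#' @param seed integer seed
#' @param n_sub number of sub-branches (default drawn from 2:6)
#' @param main_length main-branch arc length, mm (default drawn from
#'   80-150 mm)
#' @param sub_length_range sub-branch arc lengths, mm (default 15-40)
#' @param curvature turning standard deviation between successive control
#'   points, degrees (default 18)
#' @param n_markers markers placed on random main-branch points (default
#'   10, the per-patient marker count used for evaluation)
#' @param resample_step arc-length resampling step, mm
#' @return a `vessel_tree`
#' @export
generate_vessel_tree <- function(side = c("LCA", "RCA"), seed = 1,
                                 n_sub = NULL, main_length = NULL,
                                 sub_length_range = c(15, 40),
                                 curvature = 18, n_markers = 10,
                                 resample_step = 0.5) {
  side <- match.arg(side)
  if (!is.null(main_length) && any(main_length <= 0)) abort("main_length must be > 0")
  if (any(sub_length_range <= 0)) abort("sub-branch lengths must be > 0")
  with_seed(seed, {
    if (is.null(n_sub)) n_sub <- sample(2:6, 1)
    if (is.null(main_length)) main_length <- runif(1, 80, 150)
    root_label <- if (side == "LCA") "LAD" else "RCA"
    dir0 <- rnorm(3); dir0 <- dir0 / sqrt(sum(dir0^2))
    main_xyz <- smooth_curve3d(c(0, 0, 0), dir0, main_length,
                               turn_sd_deg = curvature)
    blocks <- list(tibble(x = main_xyz[, 1], y = main_xyz[, 2],
                          z = main_xyz[, 3], branch = root_label))
    branches <- tibble(id = root_label, parent = NA_character_,
                       attach = NA_integer_, class = "main",
                       main_label = root_label)
    n_pts <- nrow(main_xyz)

    if (side == "LCA") {
      # LCX leaves the LAD near the root (left-main simplification)
      ai <- max(2L, round(0.08 * n_pts))
      tangent <- main_xyz[ai + 1L, ] - main_xyz[ai - 1L, ]
      perp <- pracma_cross(tangent, rnorm(3))
      d <- perp / sqrt(sum(perp^2)) + 0.3 * tangent / sqrt(sum(tangent^2))
      lcx_len <- runif(1, 0.6, 0.9) * main_length
      lcx <- smooth_curve3d(main_xyz[ai, ], d, lcx_len, turn_sd_deg = curvature)
      blocks <- c(blocks, list(tibble(x = lcx[, 1], y = lcx[, 2], z = lcx[, 3],
                                      branch = "LCX")))
      branches <- dplyr::bind_rows(branches,
        tibble(id = "LCX", parent = root_label, attach = ai,
               class = "main", main_label = "LCX"))
    }

    pts <- dplyr::bind_rows(blocks)
    for (k in seq_len(n_sub)) {
      host_idx <- sample(which(branches$class == "main"), 1)
      host <- branches$id[host_idx]
      rows <- which(pts$branch == host)
      ai_local <- sample(seq(max(2L, round(0.1 * length(rows))),
                             round(0.9 * length(rows))), 1)
      ai <- rows[ai_local]
      p0 <- unlist(pts[ai, c("x", "y", "z")])
      tangent <- unlist(pts[min(ai + 1L, max(rows)), c("x", "y", "z")]) -
        unlist(pts[max(ai - 1L, min(rows)), c("x", "y", "z")])
      perp <- pracma_cross(tangent, rnorm(3))
      d <- perp / sqrt(sum(perp^2)) + runif(1, 0.2, 0.8) *
        tangent / sqrt(sum(tangent^2))
      len <- runif(1, sub_length_range[1], sub_length_range[2])
      sb <- smooth_curve3d(p0, d, len, turn_sd_deg = curvature, n_ctrl = 5,
                           n_dense = 80)
      bid <- sprintf("S%d", k)
      pts <- dplyr::bind_rows(pts, tibble(x = sb[, 1], y = sb[, 2],
                                          z = sb[, 3], branch = bid))
      branches <- dplyr::bind_rows(branches,
        tibble(id = bid, parent = host, attach = ai, class = "sub",
               main_label = NA_character_))
    }

    # center on the isocenter
    ctr <- colMeans(as.matrix(pts[, c("x", "y", "z")]))
    pts$x <- pts$x - ctr[1]; pts$y <- pts$y - ctr[2]; pts$z <- pts$z - ctr[3]

    main_rows <- which(pts$branch %in% branches$id[branches$class == "main"])
    marker_rows <- sort(sample(main_rows, min(n_markers, length(main_rows))))
    markers <- tibble(point = marker_rows,
                      id = sprintf("m%02d", seq_along(marker_rows)))
    tree <- vessel_tree(pts, branches, side, markers)
    tree <- label_segments(tree)
    resample_tree(tree, resample_step)
  })
}

#' Generate a synthetic PQRST-like ECG trace
#'
#' Sum-of-Gaussians beat template (P, Q, R, S, T waves) repeated with
#' beat-to-beat R-R jitter of up to 3 percent, plus white Gaussian noise at
#' the requested SNR. The exact R-peak times used are returned alongside the
#' trace.
#'
#' @param hr_bpm heart rate, 40-180 bpm
#' @param duration trace length in seconds (at least two beats)
#' @param fs sampling rate, Hz
#' @param snr_db signal-to-noise ratio of the additive noise, dB
#' @param seed integer seed
#' @return list with `trace` (an `ecg_trace`, no frame times) and
#'   `r_peaks` (true R-peak times, seconds)
#' @export
generate_ecg <- function(hr_bpm = 75, duration = 10, fs = 500, snr_db = 20,
                         seed = 1) {
  if (hr_bpm < 40 || hr_bpm > 180) abort("hr_bpm must be in [40, 180]")
  rr <- 60 / hr_bpm
  if (duration < 2 * rr) abort("duration must cover at least two beats")
  with_seed(seed, {
    t <- seq(0, duration, by = 1 / fs)[-1]
    r_times <- numeric(0)
    tt <- 0.4 * rr
    while (tt < duration - 0.4 * rr) {
      r_times <- c(r_times, tt)
      tt <- tt + rr * (1 + runif(1, -0.03, 0.03))
    }
    # (amplitude, offset fraction of rr, width s) per wave
    waves <- rbind(P = c(0.12, -0.22, 0.035),
                   Q = c(-0.10, -0.035, 0.012),
                   R = c(1.00, 0.00, 0.012),
                   S = c(-0.15, 0.035, 0.014),
                   T = c(0.30, 0.32, 0.070))
    x <- numeric(length(t))
    for (r in r_times) {
      for (w in seq_len(nrow(waves))) {
        mu <- r + waves[w, 2] * rr
        x <- x + waves[w, 1] * exp(-(t - mu)^2 / (2 * waves[w, 3]^2))
      }
    }
    p_sig <- mean(x^2)
    x <- x + rnorm(length(x), 0, sqrt(p_sig / 10^(snr_db / 10)))
    list(trace = ecg_trace(x, fs), r_peaks = r_times)
  })
}

# split a projected polyline into inside-image runs (rasterize rejects
# out-of-bounds vertices; off-detector vessel parts are simply not imaged)
clip_polyline <- function(xy, image_size) {
  inside <- xy[, 1] >= 0 & xy[, 1] <= image_size[2] - 1 &
    xy[, 2] >= 0 & xy[, 2] <= image_size[1] - 1
  if (!any(inside)) return(list())
  r <- rle(inside)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    out[[length(out) + 1L]] <- xy[starts[k]:ends[k], , drop = FALSE]
  }
  out
}

rotate2d <- function(xy, deg, center) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  sweep(sweep(xy, 2, center) %*% t(R), 2, center, FUN = "+")
}

#' Generate a complete synthetic registration case
#'
#' Draws a vessel tree, a C-arm geometry sampled from the clinical
#' acquisition ranges (primary angle -37.4 to 57.5 deg, secondary -43.5 to
#' 45 deg, SID 949-1208 mm, SOD 649-810 mm, spacing 0.244-0.293 mm/px,
#' 512 x 512 detector), and a ground-truth pose uniform within
#' `scale * (+-13 mm, +-12 deg)`. The tree is rendered through the geometry
#' under the true pose into a binary centerline mask (with optional vertex
#' jitter and an optional spurious clutter branch); the returned tree
#' carries the unperturbed pose, so `true_pose` is the registration
#' target. When the identity-pose projection would overfill the detector
#' the tree is shrunk about its centroid to 70 percent of the field of
#' view. Deterministic per seed.
#'
#' @param seed integer seed
#' @param scale perturbation scale, fraction of the search bounds in
#'   `[0, 1]`
#' @param clutter add a spurious 2D sub-branch to the mask (a copy of one
#'   true sub-branch swung about its attach point), emulating a vessel
#'   visible in the angiogram but missing from the CTA tree
#' @param noise_px standard deviation of raster vertex jitter, pixels
#' @param side vessel side; default drawn at random
#' @param th_R,d_max the bounds the perturbation is scaled against
#' @return list of class `synthetic_case`: `tree`, `geom`, `true_pose`,
#'   `centerline` (a `centerline2d`), `mask`, `ecg` (an `ecg_trace` with
#'   15 fps frame times), `r_peaks`, `cta_phase`, `center`, `seed`
#' @export
generate_case <- function(seed = 1, scale = 2 / 3, clutter = FALSE,
                          noise_px = 0, side = NULL, th_R = 12, d_max = 13) {
  if (scale < 0 || scale > 1) abort("perturbation scale must be in [0, 1]")
  tree_seed <- seed * 101L + 7L
  case <- with_seed(seed, {
    side <- if (is.null(side)) sample(c("LCA", "RCA"), 1) else side
    geom <- carm_geometry(primary_angle = runif(1, -37.4, 57.5),
                          secondary_angle = runif(1, -43.5, 45),
                          sid = runif(1, 949, 1208),
                          sod = runif(1, 649.23, 810),
                          pixel_spacing = runif(1, 0.244, 0.293),
                          image_size = c(512L, 512L))
    true_pose <- rigid_transform(t = runif(3, -1, 1) * scale * d_max,
                                 r = runif(3, -1, 1) * scale * th_R)
    hr <- runif(1, 50, 120)
    cta_phase <- runif(1)
    clutter_angle <- sample(c(-1, 1), 1) * runif(1, 25, 45)
    list(side = side, geom = geom, true_pose = true_pose, hr = hr,
         cta_phase = cta_phase, clutter_angle = clutter_angle)
  })
  tree <- generate_vessel_tree(side = case$side, seed = tree_seed)
  geom <- case$geom

  # shrink the tree if the zero-pose projection overfills the detector
  pts <- tree_points(tree)
  center <- colMeans(pts)
  proj <- project_points(pts, geom, rigid_transform(), center)
  ext <- max(diff(range(proj$x)), diff(range(proj$y)))
  fit <- 0.70 * min(geom$image_size)
  if (ext > fit) {
    shrink <- fit / ext
    tree$points$x <- center[1] + (tree$points$x - center[1]) * shrink
    tree$points$y <- center[2] + (tree$points$y - center[2]) * shrink
    tree$points$z <- center[3] + (tree$points$z - center[3]) * shrink
    pts <- tree_points(tree)
    center <- colMeans(pts)
  }

  # render the truly-posed tree, one polyline per branch
  polys <- list()
  for (bid in tree$branches$id) {
    rows <- branch_rows(tree, bid)
    pr <- project_points(pts[rows, , drop = FALSE], geom, case$true_pose, center)
    polys[[bid]] <- cbind(pr$x, pr$y)
  }
  if (clutter) {
    # spurious extra 2D sub-branch: a vessel visible in the angiogram but
    # absent from the CTA tree, emulated as a copy of one true sub-branch
    # swung about its own attach point (falls back to the distal main
    # segment when the tree has no sub-branches)
    subs <- tree$branches$id[tree$branches$class == "sub"]
    if (length(subs) > 0L) {
      sp <- polys[[subs[1]]]
    } else {
      main_id <- tree$branches$id[which(tree$branches$class == "main")[1]]
      mp <- polys[[main_id]]
      sp <- mp[round(0.6 * nrow(mp)):nrow(mp), , drop = FALSE]
    }
    polys[["clutter"]] <- rotate2d(sp, case$clutter_angle, sp[1, ])
  }
  if (noise_px > 0) {
    polys <- with_seed(seed + 1L, lapply(polys, function(p) {
      p + matrix(rnorm(length(p), 0, noise_px), ncol = 2)
    }))
  }
  polys <- unlist(lapply(polys, clip_polyline, image_size = geom$image_size),
                  recursive = FALSE)
  mask <- rasterize_polyline(polys, geom$image_size)
  cl2d <- centerline2d(mask = mask, pixel_spacing = mean(geom$pixel_spacing))

  eg <- generate_ecg(hr_bpm = case$hr, duration = 6, fs = 500, snr_db = 20,
                     seed = seed + 2L)
  frame_times <- seq(1 / 15, eg$trace$duration - 1e-9, by = 1 / 15)
  ecg <- ecg_trace(eg$trace$samples, eg$trace$fs, frame_times)

  structure(list(tree = tree, geom = geom, true_pose = case$true_pose,
                 centerline = cl2d, mask = mask, ecg = ecg,
                 r_peaks = eg$r_peaks, cta_phase = case$cta_phase,
                 center = center, seed = seed, scale = scale),
            class = "synthetic_case")
}
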