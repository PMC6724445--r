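#' Registration configuration
#'
#' Bounds and optimizer settings for the staged pose search. The rotation
#' and translation bounds (`th_R` = 12 degrees, `d_max` = 13 mm) restrict
#' every pose parameter relative to the initial-registration pose; the same
#' `d_max`, converted to pixels, caps the local distance map.
#'
#' @param th_R rotation bound, degrees per axis (default 12)
#' @param d_max translation bound, mm per axis, and distance-map cap in mm
#'   (default 13)
#' @param query_mode distance-map query used by the objective
#'   (`"bilinear"`, the default, smooths the search landscape; `"nearest"`
#'   is the plain lookup)
#' @param par_tol Powell parameter tolerance (relative to each bound)
#' @param fn_tol Powell relative function tolerance
#' @param max_iter maximum Powell iterations per stage
#' @param restarts optional seeded random restarts perturbing the start
#'   within 10 percent of the bounds (default 0: fully deterministic)
#' @param estimate_depth estimate the depth translation during initial
#'   alignment from the bounding-box diagonal ratio
#' @param margin_px optimal-boundary-box margin in pixels
#' @return object of class `registration_config`
#' @export
registration_config <- function(th_R = 12, d_max = 13,
                                query_mode = c("bilinear", "nearest"),
                                par_tol = 1e-3, fn_tol = 1e-4, max_iter = 200,
                                restarts = 0, estimate_depth = TRUE,
                                margin_px = 10) {
  stopifnot(th_R > 0, d_max > 0)
  structure(list(th_R = th_R, d_max = d_max, query_mode = match.arg(query_mode),
                 par_tol = par_tol, fn_tol = fn_tol, max_iter = max_iter,
                 restarts = restarts, estimate_depth = estimate_depth,
                 margin_px = margin_px),
            class = "registration_config")
}

#' Importance-weighted average absolute distance difference (AADD)
#'
#' The similarity measure minimized during registration:
#' `AADD = (1/N) * sum_i alpha_i * D(project(pose(P_i)))` where `D` is the
#' capped local-distance-map lookup converted to detector mm. Points that
#' project outside the image contribute `alpha_i * d_max`.
#'
#' @param points3d n x 3 matrix, patient mm
#' @param importance length-n importance weights `alpha`
#' @param geom a `carm_geometry`
#' @param pose a `rigid_transform`
#' @param map a `local_distance_map` built from the 2D centerline (pixel
#'   unit)
#' @param center rotation center for the pose
#' @param query_mode distance query mode
#' @return the AADD score in mm (detector plane)
#' @export
aadd <- function(points3d, importance, geom, pose, map, center = NULL,
                 query_mode = "nearest") {
  points3d <- as.matrix(points3d)
  if (nrow(points3d) == 0L) abort("empty point set")
  stopifnot(length(importance) == nrow(points3d))
  proj <- project_points(points3d, geom, pose, center)
  d_px <- ldm_query(map, cbind(proj$x, proj$y), mode = query_mode)
  spacing <- mean(geom$pixel_spacing)
  mean(importance * d_px * spacing)
}

# --- Powell direction-set minimizer -------------------------------------
# Derivative-free minimization: cycle over a direction set doing Brent line
# searches (stats::optimize), then replace the direction of largest decrease
# with the net displacement when the standard extrapolation test accepts it.
# Bounds are handled twice over: line searches are restricted to the box
# intersection, and the caller's objective adds a penalty outside the box.
powell_minimize <- function(par, fn, lower, upper, par_tol = 1e-3,
                            fn_tol = 1e-4, max_iter = 200) {
  n <- length(par)
  scale <- (upper - lower) / 2
  dirs <- diag(scale, n, n)[, seq_len(n), drop = FALSE]
  if (n == 1L) dirs <- matrix(scale, 1, 1)
  f0 <- fn(par)
  n_eval <- 1L
  line_min <- function(p, d) {
    # intersect the ray p + t d with [lower, upper]
    tlo <- -Inf; thi <- Inf
    for (i in seq_len(n)) {
      if (abs(d[i]) < .Machine$double.eps) next
      a <- (lower[i] - p[i]) / d[i]; b <- (upper[i] - p[i]) / d[i]
      tlo <- max(tlo, min(a, b)); thi <- min(thi, max(a, b))
    }
    if (!is.finite(tlo) || !is.finite(thi) || thi - tlo < 1e-12) {
      return(list(p = p, f = fn(p), used = 1L))
    }
    g <- function(t) fn(p + t * d)
    opt <- optimize(g, c(tlo, thi), tol = par_tol)
    used <- 30L  # optimize() does not report call counts; Brent ~ 25-35
    if (opt$objective < g(0)) {
      list(p = p + opt$minimum * d, f = opt$objective, used = used + 1L)
    } else {
      list(p = p, f = g(0), used = used + 2L)
    }
  }
  best_p <- par; best_f <- f0
  for (iter in seq_len(max_iter)) {
    p_start <- par; f_start <- f0
    biggest <- 0; ibig <- 1L
    for (k in seq_len(ncol(dirs))) {
      res <- line_min(par, dirs[, k])
      n_eval <- n_eval + res$used
      dec <- f0 - res$f
      if (dec > biggest) { biggest <- dec; ibig <- k }
      par <- res$p; f0 <- res$f
    }
    if (f0 < best_f) { best_f <- f0; best_p <- par }
    if (2 * (f_start - f0) <= fn_tol * (abs(f_start) + abs(f0)) + 1e-12) break
    # extrapolated point along the net displacement
    p_ext <- pmin(upper, pmax(lower, 2 * par - p_start))
    f_ext <- fn(p_ext); n_eval <- n_eval + 1L
    if (f_ext < f_start) {
      t1 <- 2 * (f_start - 2 * f0 + f_ext) * (f_start - f0 - biggest)^2
      t2 <- biggest * (f_start - f_ext)^2
      if (t1 < t2) {
        d_new <- par - p_start
        if (sqrt(sum(d_new^2)) > 1e-12) {
          res <- line_min(par, d_new)
          n_eval <- n_eval + res$used
          if (res$f < f0) { par <- res$p; f0 <- res$f }
          dirs[, ibig] <- d_new
        }
      }
    }
    if (f0 < best_f) { best_f <- f0; best_p <- par }
  }
  list(par = best_p, value = best_f, n_eval = n_eval, iterations = iter)
}

#' Optimize a subset of pose parameters with bounded Powell search
#'
#' Runs Powell direction-set minimization over the named free parameters
#' only, holding the rest at their `start` values. Every candidate is kept
#' inside the box `|T| <= d_max`, `|R| <= th_R` relative to `origin` (the
#' initial-registration pose): line searches are restricted to the box and,
#' as a safety net, out-of-box candidates are penalized by
#' `d_max * (1 + excess)` so the search is driven back inside rather than
#' stalling on a clamp-induced plateau. The result is never worse than the
#' start.
#'
#' @param free_params character subset of
#'   `c("Tx","Ty","Tz","Rx","Ry","Rz")`
#' @param start a `rigid_transform` within bounds
#' @param objective function of a `rigid_transform` returning the AADD
#' @param config a `registration_config`
#' @param origin the pose the bounds are centered on (default `start`)
#' @return list with `pose`, `value`, `n_eval`
#' @export
optimize_stage <- function(free_params, start, objective, config,
                           origin = start) {
  all_names <- c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz")
  stopifnot(all(free_params %in% all_names))
  free <- match(free_params, all_names)
  start_vec <- c(start$t, start$r)
  origin_vec <- c(origin$t, origin$r)
  bound <- c(rep(config$d_max, 3), rep(config$th_R, 3))
  lower <- origin_vec - bound
  upper <- origin_vec + bound
  if (any(start_vec < lower - 1e-9 | start_vec > upper + 1e-9)) {
    abort("start pose outside the search bounds")
  }
  vec_to_pose <- function(v) {
    full <- start_vec; full[free] <- v
    rigid_transform(t = full[1:3], r = full[4:6])
  }
  pen <- function(v) {
    excess <- sum(pmax(0, v - upper[free]) + pmax(0, lower[free] - v)) /
      mean(bound[free])
    if (excess > 0) config$d_max * (1 + excess) else 0
  }
  fn <- function(v) objective(vec_to_pose(v)) + pen(v)
  f_start <- fn(start_vec[free])
  if (!is.finite(f_start)) abort("objective non-finite at start")
  res <- powell_minimize(start_vec[free], fn, lower[free], upper[free],
                         par_tol = config$par_tol * mean(bound[free]),
                         fn_tol = config$fn_tol, max_iter = config$max_iter)
  if (res$value > f_start) { res$par <- start_vec[free]; res$value <- f_start }
  list(pose = vec_to_pose(res$par), value = res$value, n_eval = res$n_eval)
}

#' Register a 3D centerline tree onto a 2D centerline
#'
#' Full fine-registration pipeline for one XA frame: bounding-box
#' translation initialization, capped local distance map construction, then
#' two Powell stages — translation-only `(Tx, Ty, Tz)` followed by the full
#' rigid six-parameter search — minimizing the importance-weighted AADD.
#' All stage searches are bounded relative to the initial pose
#' (`|T| <= d_max`, `|R| <= th_R`).
#'
#' @param tree a `vessel_tree` with importance assigned (see
#'   [assign_importance()]); trees with unassigned importance are registered
#'   with uniform weights and a message
#' @param centerline a `centerline2d` (or binary mask matrix)
#' @param geom a `carm_geometry`
#' @param config a `registration_config`
#' @return object of class `registration_result`: fields `pose` (the
#'   refined `rigid_transform`), `initial_pose`, `final_aadd`, `trace`
#'   (tibble of per-stage AADD), `n_eval`, `projected` (tibble `x`, `y`,
#'   `depth` of the registered centerline for depth-colored display),
#'   `center` (rotation center used), `geom`, `config`
#' @export
register_vessels <- function(tree, centerline, geom,
                             config = registration_config()) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(geom, "carm_geometry"))
  if (!inherits(centerline, "centerline2d")) {
    centerline <- centerline2d(mask = centerline,
                               pixel_spacing = mean(geom$pixel_spacing))
  }
  pts <- tree_points(tree)
  alpha <- tree$points$alpha
  if (all(is.na(alpha))) {
    inform("importance unassigned; registering with uniform weights")
    alpha <- rep(1, nrow(pts))
  }
  center <- colMeans(pts)
  spacing <- mean(geom$pixel_spacing)

  # initial registration: DICOM angles fix rotation/scale; boxes fix T
  proj0 <- project_points(pts, geom, rigid_transform(), center)
  box3 <- expand_box(bounding_box(cbind(proj0$x, proj0$y)), config$margin_px)
  box2 <- expand_box(bounding_box(mask_pixels(centerline$mask)), config$margin_px)
  pose0 <- initial_translation(box3, box2, geom,
                               estimate_depth = config$estimate_depth)

  d_max_px <- config$d_max / spacing
  map <- build_local_distance_map(centerline$mask, d_max_px)

  objective <- function(pose) {
    aadd(pts, alpha, geom, pose, map, center, query_mode = config$query_mode)
  }
  f_init <- objective(pose0)
  s1 <- optimize_stage(c("Tx", "Ty", "Tz"), pose0, objective, config,
                       origin = pose0)
  s2 <- optimize_stage(c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz"), s1$pose,
                       objective, config, origin = pose0)
  # objective values include a zero penalty inside the box; re-evaluate raw
  a1 <- objective(s1$pose); a2 <- objective(s2$pose)
  trace <- tibble(stage = c("initial", "translation", "rigid"),
                  aadd = cummin(c(f_init, a1, a2)))
  final_pose <- if (a2 <= a1) s2$pose else s1$pose
  proj <- project_points(pts, geom, final_pose, center)
  structure(list(pose = final_pose, initial_pose = pose0,
                 final_aadd = min(a1, a2), trace = trace,
                 n_eval = s1$n_eval + s2$n_eval + 1L,
                 projected = proj, center = center, geom = geom,
                 config = config, centerline = centerline),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n")
  cat(sprintf("  pose: T = (%.3g, %.3g, %.3g) mm, R = (%.3g, %.3g, %.3g) deg\n",
              x$pose$t[1], x$pose$t[2], x$pose$t[3],
              x$pose$r[1], x$pose$r[2], x$pose$r[3]))
  cat(sprintf("  AADD: %s (initial -> translation -> rigid)\n",
              paste(signif(x$trace$aadd, 4), collapse = " -> ")))
  cat(sprintf("  %d objective evaluations\n", x$n_eval))
  invisible(x)
}

#' Tidy a registration result into one row per pose parameter
#' @param x a `registration_result`
#' @param ... unused
#' @return tibble with `term`, `estimate`, `unit` and `bound` (the
#'   half-width of the search box around the initial pose)
#' @export
tidy.registration_result <- function(x, ...) {
  tibble(term = c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz"),
         estimate = c(x$pose$t, x$pose$r),
         unit = rep(c("mm", "deg"), each = 3),
         bound = rep(c(x$config$d_max, x$config$th_R), each = 3))
}

#' One-row summary of a registration result
#' @param x a `registration_result`
#' @param ... unused
#' @return a one-row tibble with initial and final AADD, the number of
#'   objective evaluations and the number of registered points
#' @export
glance.registration_result <- function(x, ...) {
  tibble(initial_aadd = x$trace$aadd[1], final_aadd = x$final_aadd,
         n_eval = x$n_eval, n_points = nrow(x$projected))
}
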