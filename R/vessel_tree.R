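#' Construct a 3D vessel centerline tree
#'
#' A `vessel_tree` stores a branch-labelled polyline tree in patient
#' coordinates (mm). Points are held as one tibble, grouped contiguously by
#' branch in branch-table order, each branch ordered root-to-tip. Branches
#' form a tree: exactly one branch has no parent (the root main branch);
#' every other branch records the global row index of the parent point it
#' attaches to.
#'
#' @param points tibble or data frame with numeric columns `x`, `y`, `z`
#'   (mm) and a `branch` column naming the owning branch. Optional columns:
#'   `segment` (`"proximal"|"mid"|"distal"`, main branches only) and `alpha`
#'   (importance in `[alpha_min, alpha_max]`).
#' @param branches tibble with columns `id`, `parent` (`NA` for the root),
#'   `attach` (global row index into `points` of the parent attachment
#'   point; `NA` for the root), `class` (`"main"` or `"sub"`), and
#'   `main_label` (`"RCA"|"LAD"|"LCX"` for main branches, else `NA`).
#'   Optional logical column `active` (sub-branch activity; `NA` until
#'   classified).
#' @param side `"LCA"` or `"RCA"`.
#' @param markers optional tibble with columns `point` (global row index)
#'   and `id` (marker label).
#' @return an object of class `vessel_tree`.
#' @export
vessel_tree <- function(points, branches, side, markers = NULL) {
  points <- as_tibble(points)
  branches <- as_tibble(branches)
  stopifnot(all(c("x", "y", "z", "branch") %in% names(points)),
            all(c("id", "parent", "attach", "class") %in% names(branches)))
  if (nrow(points) == 0L) abort("empty tree")
  xyz <- as.matrix(points[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("non-finite coordinates in vessel tree")
  if (!side %in% c("LCA", "RCA")) abort("side must be 'LCA' or 'RCA'")
  if (!"segment" %in% names(points)) points$segment <- NA_character_
  if (!"alpha" %in% names(points)) points$alpha <- NA_real_
  if (!"main_label" %in% names(branches)) branches$main_label <- NA_character_
  if (!"active" %in% names(branches)) branches$active <- NA
  # contiguity + ordering: points must appear grouped by branch, in branch order
  rle_b <- rle(points$branch)$values
  if (anyDuplicated(rle_b) || !identical(rle_b, branches$id[branches$id %in% rle_b]) ||
      !setequal(rle_b, branches$id)) {
    abort("points must be grouped contiguously by branch, in branch-table order")
  }
  n_root <- sum(is.na(branches$parent))
  if (n_root != 1L) abort("tree must have exactly one root branch (parent = NA)")
  if (!is.na(branches$attach[is.na(branches$parent)])) {
    abort("root branch must have attach = NA")
  }
  non_root <- !is.na(branches$parent)
  if (any(non_root)) {
    if (any(!branches$parent[non_root] %in% branches$id)) abort("unknown parent branch id")
    att <- branches$attach[non_root]
    if (any(is.na(att)) || any(att < 1L) || any(att > nrow(points))) {
      abort("attach indices must be valid rows of points")
    }
    if (any(points$branch[att] != branches$parent[non_root])) {
      abort("attach index must lie on the parent branch")
    }
  }
  if (!is.null(markers)) {
    markers <- as_tibble(markers)
    stopifnot(all(c("point", "id") %in% names(markers)))
    if (any(markers$point < 1L | markers$point > nrow(points))) {
      abort("marker point index out of range")
    }
  } else {
    markers <- tibble(point = integer(), id = character())
  }
  structure(list(points = points, branches = branches, side = side,
                 markers = markers),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> side=%s  %d branches (%d main), %d points, %d markers\n",
              x$side, nrow(x$branches), sum(x$branches$class == "main"),
              nrow(x$points), nrow(x$markers)))
  cat(sprintf("  importance: %s\n",
              if (all(is.na(x$points$alpha))) "unassigned" else
                sprintf("[%.3g, %.3g]", min(x$points$alpha), max(x$points$alpha))))
  invisible(x)
}

#' Row indices of a branch within the tree's point table
#' @param tree a `vessel_tree`
#' @param branch_id a branch id
#' @return integer vector of global row indices, root-to-tip order
#' @export
branch_rows <- function(tree, branch_id) which(tree$points$branch == branch_id)

#' Matrix of 3D coordinates of a tree
#' @param tree a `vessel_tree`
#' @return n x 3 numeric matrix (mm)
#' @export
tree_points <- function(tree) {
  unname(as.matrix(tree$points[, c("x", "y", "z")]))
}

#' Cumulative arc length along a polyline
#' @param xyz n x k coordinate matrix
#' @return numeric vector of length n, starting at 0
#' @keywords internal
cum_arclength <- function(xyz) {
  if (nrow(xyz) == 1L) return(0)
  seg <- sqrt(rowSums(diff(xyz)^2))
  c(0, cumsum(seg))
}

resample_polyline <- function(xyz, step) {
  s <- cum_arclength(xyz)
  L <- s[length(s)]
  if (L == 0) return(xyz[c(1L, nrow(xyz)), , drop = FALSE])
  n_seg <- max(1L, ceiling(L / step - 1e-12))
  s_new <- seq(0, L, length.out = n_seg + 1L)
  out <- vapply(seq_len(ncol(xyz)),
                function(j) approx(s, xyz[, j], xout = s_new, ties = "ordered")$y,
                numeric(n_seg + 1L))
  matrix(out, ncol = ncol(xyz))
}

#' Resample every branch of a tree by arc length
#'
#' Each branch whose maximum consecutive-point spacing exceeds `step` is
#' resampled at uniform arc-length spacing no larger than `step`; branches
#' already sampled at or below `step` are left untouched (which makes the
#' operation exactly idempotent and never invents resolution). Branch
#' topology, labels, attach points and markers are preserved; attach points
#' and markers are snapped to the nearest resampled point.
#'
#' @param tree a `vessel_tree`
#' @param step maximum spacing in mm (`> 0`); default 0.5 mm, below typical
#'   CTA slice thickness so no information is invented
#' @return the resampled `vessel_tree`
#' @export
resample_tree <- function(tree, step = 0.5) {
  stopifnot(inherits(tree, "vessel_tree"))
  if (!is.finite(step) || step <= 0) abort("step must be > 0")
  old_pts <- tree$points
  marker_xyz <- as.matrix(old_pts[tree$markers$point, c("x", "y", "z"), drop = FALSE])
  attach_xyz <- lapply(seq_len(nrow(tree$branches)), function(i) {
    a <- tree$branches$attach[i]
    if (is.na(a)) NULL else unlist(old_pts[a, c("x", "y", "z")])
  })

  new_blocks <- list()
  for (i in seq_len(nrow(tree$branches))) {
    bid <- tree$branches$id[i]
    rows <- which(old_pts$branch == bid)
    xyz <- as.matrix(old_pts[rows, c("x", "y", "z")])
    if (nrow(xyz) < 2L) abort(sprintf("branch '%s' has fewer than 2 points", bid))
    spacing <- sqrt(rowSums(diff(xyz)^2))
    s_all <- cum_arclength(xyz)
    n_target <- ceiling(s_all[length(s_all)] / step - 1e-12) + 1L
    # resample only when the branch is under-resolved (spacing above the
    # step) or over-resolved relative to the step; an already conforming
    # branch is left untouched, which keeps the operation exactly idempotent
    if (max(spacing) > step + 1e-12 || nrow(xyz) > n_target) {
      new_xyz <- resample_polyline(xyz, step)
      seg <- old_pts$segment[rows]
      # carry segment labels by nearest original arc position
      s_old <- cum_arclength(xyz); s_new <- cum_arclength(new_xyz)
      # map via relative arc position
      idx <- vapply(s_new, function(v) which.min(abs(s_old - v)), integer(1))
      seg_new <- seg[idx]
    } else {
      new_xyz <- xyz
      seg_new <- old_pts$segment[rows]
    }
    new_blocks[[i]] <- tibble(x = new_xyz[, 1], y = new_xyz[, 2], z = new_xyz[, 3],
                              branch = bid, segment = seg_new, alpha = NA_real_)
  }
  new_pts <- dplyr::bind_rows(new_blocks)

  nearest_row <- function(xyz_target, branch_id) {
    rows <- which(new_pts$branch == branch_id)
    block <- as.matrix(new_pts[rows, c("x", "y", "z")])
    d2 <- colSums((t(block) - xyz_target)^2)
    rows[which.min(d2)]
  }
  branches <- tree$branches
  for (i in seq_len(nrow(branches))) {
    if (!is.na(branches$parent[i])) {
      branches$attach[i] <- nearest_row(attach_xyz[[i]], branches$parent[i])
    }
  }
  markers <- tree$markers
  if (nrow(markers) > 0L) {
    old_branch <- old_pts$branch[markers$point]
    markers$point <- vapply(seq_len(nrow(markers)), function(k) {
      nearest_row(marker_xyz[k, ], old_branch[k])
    }, integer(1))
  }
  vessel_tree(new_pts, branches, tree$side, markers)
}

#' Bifurcation points of a tree
#'
#' Returns the 3D coordinates of the attachment points of every non-root
#' branch, with coincident attach points deduplicated. A single-branch tree
#' has no bifurcations.
#'
#' @param tree a `vessel_tree`
#' @return tibble with columns `x`, `y`, `z` (mm), possibly zero rows
#' @export
extract_bifurcations <- function(tree) {
  stopifnot(inherits(tree, "vessel_tree"))
  att <- tree$branches$attach[!is.na(tree$branches$parent)]
  att <- unique(att[!is.na(att)])
  # distinct indices can still carry coincident coordinates
  out <- dplyr::distinct(tree$points[att, c("x", "y", "z")])
  as_tibble(out)
}

#' Total arc length of a tree or one branch
#' @param tree a `vessel_tree`
#' @param branch_id optional branch id; default sums all branches
#' @return length in mm
#' @export
tree_arclength <- function(tree, branch_id = NULL) {
  ids <- if (is.null(branch_id)) tree$branches$id else branch_id
  sum(vapply(ids, function(b) {
    xyz <- as.matrix(tree$points[branch_rows(tree, b), c("x", "y", "z")])
    s <- cum_arclength(xyz)
    s[length(s)]
  }, numeric(1)))
}
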