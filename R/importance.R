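#' Label main-branch points proximal/mid/distal by arc-length thirds
#'
#' SCCT-style segment labels are normally supplied with the centerline; when
#' they are absent this helper splits each main branch into equal arc-length
#' thirds, which is the rule the synthetic generator uses.
#'
#' @param tree a `vessel_tree`
#' @param overwrite relabel even if segment labels already exist
#' @return the tree with `segment` filled on every main-branch point
#' @export
label_segments <- function(tree, overwrite = FALSE) {
  for (i in which(tree$branches$class == "main")) {
    bid <- tree$branches$id[i]
    rows <- branch_rows(tree, bid)
    if (!overwrite && !anyNA(tree$points$segment[rows])) next
    s <- cum_arclength(as.matrix(tree$points[rows, c("x", "y", "z")]))
    frac <- s / max(s[length(s)], .Machine$double.eps)
    tree$points$segment[rows] <- ifelse(frac < 1 / 3, "proximal",
                                        ifelse(frac < 2 / 3, "mid", "distal"))
  }
  tree
}

# ultimate main-branch ancestor of a branch and the attach row on that main
main_attachment <- function(tree, branch_idx) {
  br <- tree$branches
  i <- branch_idx
  attach <- br$attach[i]
  repeat {
    parent <- br$parent[i]
    if (is.na(parent)) abort("root branch has no main attachment")
    pi <- match(parent, br$id)
    if (br$class[pi] == "main") return(list(main_idx = pi, attach = attach))
    # sub attached to a sub: climb, inheriting the parent's own attachment
    attach <- br$attach[pi]
    i <- pi
  }
}

#' Classify sub-branches as active or inactive
#'
#' Each sub-branch belongs to an anatomical area: the SCCT segment
#' (proximal/mid/distal) of the point where it — or, for a sub-branch of a
#' sub-branch, its ultimate ancestor — attaches to a main branch. Within
#' each (main branch, segment) area, sub-branches count as active while the
#' number of sub-branches in that area stays at or below the reference count
#' for the segment; any excess is marked inactive, dropping the sub-branches
#' farthest from the main-branch root first. Areas with few, mutually
#' consistent sub-branches are thus kept at full weight while crowded,
#' ambiguous areas are down-weighted.
#'
#' @param tree a `vessel_tree` with segment labels on all main branches
#' @param reference_counts named numeric vector of expected sub-branch
#'   counts per segment; default `c(proximal = 2, mid = 2, distal = 1)`
#' @return the tree with `active` set on every sub-branch
#' @export
classify_subbranches <- function(tree,
                                 reference_counts = c(proximal = 2, mid = 2, distal = 1)) {
  stopifnot(inherits(tree, "vessel_tree"))
  sub_idx <- which(tree$branches$class == "sub")
  if (length(sub_idx) == 0L) return(tree)
  main_rows <- tree$points$branch %in% tree$branches$id[tree$branches$class == "main"]
  if (anyNA(tree$points$segment[main_rows])) {
    abort("main branch lacks segment labels; run label_segments() first")
  }
  info <- lapply(sub_idx, function(i) main_attachment(tree, i))
  main_of <- vapply(info, function(a) a$main_idx, integer(1))
  attach_of <- vapply(info, function(a) as.integer(a$attach), integer(1))
  area <- tree$points$segment[attach_of]
  # arc position of the attachment along its main branch (for the excess order)
  arcpos <- vapply(seq_along(sub_idx), function(k) {
    rows <- branch_rows(tree, tree$branches$id[main_of[k]])
    s <- cum_arclength(as.matrix(tree$points[rows, c("x", "y", "z")]))
    s[match(attach_of[k], rows)]
  }, numeric(1))

  tree$branches$active[sub_idx] <- TRUE
  key <- paste(main_of, area)
  for (g in unique(key)) {
    members <- which(key == g)
    ref <- reference_counts[[area[members[1]]]]
    excess <- length(members) - ref
    if (excess > 0) {
      drop <- members[order(arcpos[members], decreasing = TRUE)][seq_len(excess)]
      tree$branches$active[sub_idx[drop]] <- FALSE
    }
  }
  # a sub of an inactive sub is itself inactive
  for (i in sub_idx) {
    pi <- match(tree$branches$parent[i], tree$branches$id)
    if (tree$branches$class[pi] == "sub" && isFALSE(tree$branches$active[pi])) {
      tree$branches$active[i] <- FALSE
    }
  }
  tree
}

#' Assign anatomical importance values to every centerline point
#'
#' Main-branch points receive an importance value interpolated linearly in
#' normalized arc length from `alpha_max` at the proximal end to `alpha_min`
#' at the distal tip. Active sub-branches start at the importance of their
#' attachment point and decay linearly with arc length at `decay` per mm,
#' floored at `alpha_min`. Inactive sub-branches get `alpha_min` everywhere.
#' All values are clamped to `[alpha_min, alpha_max]`.
#'
#' @param tree a `vessel_tree` whose sub-branches are classified
#'   (see [classify_subbranches()])
#' @param alpha_max importance at the proximal end of a main branch (1.0)
#' @param alpha_min floor importance (0.1)
#' @param decay active sub-branch decay rate per mm (default 0.02)
#' @return the tree with `alpha` set on every point
#' @export
assign_importance <- function(tree, alpha_max = 1.0, alpha_min = 0.1, decay = 0.02) {
  stopifnot(inherits(tree, "vessel_tree"))
  br <- tree$branches
  if (any(br$class == "sub" & is.na(br$active))) {
    abort("sub-branches are unclassified; run classify_subbranches() first")
  }
  # process parents before children so attach alphas exist
  order_idx <- integer(0)
  remaining <- seq_len(nrow(br))
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(i) {
      is.na(br$parent[i]) || match(br$parent[i], br$id) %in% order_idx
    }, logical(1))]
    if (length(ready) == 0L) abort("branch parent cycle")
    order_idx <- c(order_idx, ready)
    remaining <- setdiff(remaining, ready)
  }
  for (i in order_idx) {
    rows <- branch_rows(tree, br$id[i])
    xyz <- as.matrix(tree$points[rows, c("x", "y", "z")])
    s <- cum_arclength(xyz)
    if (br$class[i] == "main") {
      frac <- s / max(s[length(s)], .Machine$double.eps)
      a <- alpha_max - (alpha_max - alpha_min) * frac
    } else if (isTRUE(br$active[i])) {
      a0 <- tree$points$alpha[br$attach[i]]
      a <- a0 - decay * s
    } else {
      a <- rep(alpha_min, length(s))
    }
    tree$points$alpha[rows] <- pmin(alpha_max, pmax(alpha_min, a))
  }
  tree
}
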