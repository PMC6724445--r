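test_that("arc-length resampling hits the requested spacing and degenerate cases", {
  tr <- resample_tree(straight_tree(length_mm = 10, n = 2), step = 1)
  expect_equal(nrow(tr$points), 11L)
  expect_equal(diff(tr$points$x), rep(1, 10))

  # step larger than the branch: endpoints only
  tr2 <- resample_tree(straight_tree(length_mm = 10, n = 5), step = 50)
  expect_equal(nrow(tr2$points), 2L)
  expect_equal(range(tr2$points$x), c(0, 10))
})

test_that("resampling a smooth multi-branch tree preserves arc length and topology", {
  tree <- generate_vessel_tree("RCA", seed = 11, n_sub = 2, resample_step = 5)
  len_before <- tree_arclength(tree)
  fine <- resample_tree(tree, 0.5)
  len_after <- tree_arclength(fine)
  expect_lt(abs(len_after - len_before) / len_before, 0.01)
  for (bid in fine$branches$id) {
    xyz <- as.matrix(fine$points[branch_rows(fine, bid), c("x", "y", "z")])
    expect_lte(max(sqrt(rowSums(diff(xyz)^2))), 0.5 + 1e-9)
  }
  expect_identical(fine$branches$id, tree$branches$id)
  expect_identical(fine$branches$parent, tree$branches$parent)
  # attach points stay on the parent branch near their old coordinates
  for (i in which(!is.na(fine$branches$parent))) {
    old_xyz <- unlist(tree$points[tree$branches$attach[i], c("x", "y", "z")])
    new_xyz <- unlist(fine$points[fine$branches$attach[i], c("x", "y", "z")])
    expect_lt(sqrt(sum((old_xyz - new_xyz)^2)), 5)
    expect_identical(fine$points$branch[fine$branches$attach[i]],
                     fine$branches$parent[i])
  }
})

test_that("resampling is idempotent at a fixed step", {
  tree <- generate_vessel_tree("LCA", seed = 4, resample_step = 2)
  once <- resample_tree(tree, 0.5)
  twice <- resample_tree(once, 0.5)
  expect_equal(tree_points(twice), tree_points(once), tolerance = 1e-12)
})

test_that("resampling rejects invalid input", {
  expect_error(resample_tree(straight_tree(), step = 0), "step")
  bad <- straight_tree()
  bad$points$x[1] <- NaN
  expect_error(vessel_tree(bad$points, bad$branches, bad$side), "non-finite")
  expect_error(vessel_tree(bad$points[0, ], bad$branches, bad$side), "empty tree")
})

test_that("bifurcation extraction returns deduplicated attach coordinates", {
  expect_equal(nrow(extract_bifurcations(straight_tree())), 0L)
  expect_equal(nrow(extract_bifurcations(forked_tree(attach_at = c(4, 7)))), 2L)

  # five sub-branches, two sharing an attach point: 4 unique coordinates
  tr <- forked_tree(attach_at = c(2, 4, 4, 6, 8))
  bif <- extract_bifurcations(tr)
  # oracle: brute-force set of attach coordinates
  att <- tr$branches$attach[!is.na(tr$branches$parent)]
  oracle <- unique(as.matrix(tr$points[att, c("x", "y", "z")]))
  expect_equal(nrow(bif), nrow(oracle))
  expect_equal(nrow(bif), 4L)
})

test_that("rasterization draws 8-connected chains and flags out-of-bounds vertices", {
  m <- rasterize_polyline(cbind(c(10, 10), c(10, 20)), c(64, 64))
  expect_equal(sum(m), 11L)
  expect_true(all(m[cbind(11:21, 11)] == 1L))

  expect_equal(sum(rasterize_polyline(cbind(5, 7), c(64, 64))), 1L)

  # every consecutive pixel pair along a traced segment is 8-connected
  set.seed(42)
  chain <- cbind(runif(50, 0, 63), runif(50, 0, 63))
  for (i in seq_len(nrow(chain) - 1)) {
    px <- vesselreg:::trace_segment(round(chain[i, ]), round(chain[i + 1, ]))
    if (nrow(px) > 1) expect_lte(max(apply(abs(diff(px)), 1, max)), 1)
  }
  m2 <- rasterize_polyline(chain, c(64, 64))
  expect_true(sum(m2) > 50)

  expect_error(rasterize_polyline(cbind(c(1, 100), c(1, 1)), c(64, 64)),
               "outside")
})
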