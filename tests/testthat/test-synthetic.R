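test_that("tree generation is deterministic per seed and respects parameters", {
  a <- generate_vessel_tree("LCA", seed = 3)
  b <- generate_vessel_tree("LCA", seed = 3)
  expect_identical(a, b)
  expect_false(identical(tree_points(a),
                         tree_points(generate_vessel_tree("LCA", seed = 4))))

  solo <- generate_vessel_tree("RCA", seed = 1, n_sub = 0)
  expect_equal(nrow(solo$branches), 1L)
  expect_error(generate_vessel_tree("RCA", main_length = -5), "main_length")
})

test_that("generated trees satisfy spacing and length contracts", {
  for (seed in 1:10) {
    side <- if (seed %% 2 == 0) "LCA" else "RCA"
    tr <- generate_vessel_tree(side, seed = seed, main_length = 110,
                               sub_length_range = c(15, 40))
    root <- tr$branches$id[is.na(tr$branches$parent)]
    expect_equal(tree_arclength(tr, root), 110, tolerance = 0.02)
    for (bid in tr$branches$id) {
      xyz <- as.matrix(tr$points[branch_rows(tr, bid), c("x", "y", "z")])
      expect_lte(max(sqrt(rowSums(diff(xyz)^2))), 0.5 + 1e-9)
    }
    subs <- tr$branches$id[tr$branches$class == "sub"]
    for (sb in subs) {
      expect_gte(tree_arclength(tr, sb), 15 * 0.98)
      expect_lte(tree_arclength(tr, sb), 40 * 1.02)
    }
    # segment labels cover all main points
    main_rows <- tr$points$branch %in% tr$branches$id[tr$branches$class == "main"]
    expect_false(anyNA(tr$points$segment[main_rows]))
  }
})

test_that("synthetic ECG carries its stated beat structure", {
  eg <- generate_ecg(hr_bpm = 60, duration = 10, fs = 500, snr_db = 40,
                     seed = 2)
  expect_true(abs(length(eg$r_peaks) - 10) <= 1)
  rr <- diff(eg$r_peaks)
  expect_true(all(abs(rr - 1) <= 0.031))
  expect_identical(generate_ecg(seed = 9)$trace$samples,
                   generate_ecg(seed = 9)$trace$samples)
  expect_error(generate_ecg(hr_bpm = 300), "hr_bpm")
  expect_error(generate_ecg(hr_bpm = 60, duration = 1), "duration")
})

test_that("case generation is deterministic and scale-0 reproduces the identity projection", {
  a <- generate_case(seed = 7, scale = 0)
  b <- generate_case(seed = 7, scale = 0)
  expect_identical(a$mask, b$mask)
  expect_identical(a$true_pose, b$true_pose)
  expect_equal(a$true_pose$t, c(0, 0, 0))
  expect_equal(a$true_pose$r, c(0, 0, 0))

  # the mask equals re-rendering the unperturbed projection
  pts <- tree_points(a$tree)
  polys <- lapply(a$tree$branches$id, function(bid) {
    pr <- project_points(pts[branch_rows(a$tree, bid), , drop = FALSE],
                         a$geom, rigid_transform(), a$center)
    cbind(pr$x, pr$y)
  })
  polys <- unlist(lapply(polys, vesselreg:::clip_polyline,
                         image_size = a$geom$image_size), recursive = FALSE)
  expect_identical(a$mask, rasterize_polyline(polys, a$geom$image_size))
})

test_that("drawn geometries and poses stay inside the clinical and bound ranges", {
  for (seed in 1:8) {
    cs <- generate_case(seed = seed, scale = 2 / 3)
    g <- cs$geom
    expect_true(g$primary_angle >= -37.4 && g$primary_angle <= 57.5)
    expect_true(g$secondary_angle >= -43.5 && g$secondary_angle <= 45)
    expect_true(g$sid >= 949 && g$sid <= 1208)
    expect_true(g$sod >= 649 && g$sod <= 810)
    expect_true(all(g$pixel_spacing >= 0.244 & g$pixel_spacing <= 0.293))
    expect_true(all(abs(cs$true_pose$t) <= 13 & abs(cs$true_pose$r) <= 12))
    expect_gt(sum(cs$mask), 100)
  }
})

test_that("clutter adds mask pixels without touching the tree or pose", {
  clean <- generate_case(seed = 3, scale = 1 / 2)
  dirty <- generate_case(seed = 3, scale = 1 / 2, clutter = TRUE)
  expect_identical(clean$tree, dirty$tree)
  expect_identical(clean$true_pose, dirty$true_pose)
  expect_gt(sum(dirty$mask), sum(clean$mask))
})
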