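test_that("AADD is the importance-weighted mean of capped map distances", {
  f <- aadd_fixture()
  # hand evaluation: (1*2 + 0.5*4 + 0.1*10)/3 with 1 mm/px spacing
  score <- aadd(f$pts, c(1, 0.5, 0.1), f$geom, rigid_transform(), f$map,
                center = c(0, 0, 0))
  expect_equal(score, 5 / 3, tolerance = 1e-9)

  # perfect overlap scores zero
  zero_map <- f$map; zero_map$grid[] <- 0
  expect_equal(aadd(f$pts, c(1, 1, 1), f$geom, rigid_transform(), zero_map,
                    center = c(0, 0, 0)), 0)

  # all points beyond the cap saturate at d_max
  sat_map <- f$map; sat_map$grid[] <- 20
  expect_equal(aadd(f$pts, c(1, 1, 1), f$geom, rigid_transform(), sat_map,
                    center = c(0, 0, 0)), 20)
  expect_error(aadd(f$pts[0, ], numeric(0), f$geom, rigid_transform(), f$map),
               "empty")
})

test_that("points projecting off the detector contribute alpha * d_max", {
  f <- aadd_fixture()
  far <- rbind(patient_from_camera(c(100, 0, 500), f$geom))  # x px = 205
  expect_equal(aadd(far, 0.5, f$geom, rigid_transform(), f$map,
                    center = c(0, 0, 0)), 0.5 * 20)
})

test_that("bounded Powell finds interior and boundary minima of known objectives", {
  cfg <- registration_config(par_tol = 1e-5, fn_tol = 1e-10)
  start <- rigid_transform()
  # quadratic with interior minimum at Tx = 5
  obj <- function(pose) (pose$t[1] - 5)^2
  res <- optimize_stage("Tx", start, obj, cfg)
  expect_equal(res$pose$t[1], 5, tolerance = 1e-2)
  expect_equal(res$pose$t[2:3], c(0, 0))

  # minimum outside the box at Tx = 20: lands on the 13 mm boundary
  obj2 <- function(pose) (pose$t[1] - 20)^2
  res2 <- optimize_stage("Tx", start, obj2, cfg)
  expect_equal(res2$pose$t[1], 13, tolerance = 1e-2)

  # already optimal start is returned unchanged
  obj3 <- function(pose) sum(pose$t^2)
  res3 <- optimize_stage(c("Tx", "Ty", "Tz"), start, obj3, cfg)
  expect_equal(res3$pose$t, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(res3$value, 0)

  # multi-parameter quadratic
  obj4 <- function(pose) sum((pose$t - c(3, -4, 6))^2) + sum((pose$r - 2)^2)
  res4 <- optimize_stage(c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz"), start, obj4, cfg)
  expect_equal(res4$pose$t, c(3, -4, 6), tolerance = 0.05)
  expect_equal(res4$pose$r, c(2, 2, 2), tolerance = 0.05)

  expect_error(optimize_stage("Tx", start, function(pose) NaN, cfg),
               "non-finite")
  expect_error(optimize_stage("Tx", rigid_transform(t = c(99, 0, 0)),
                              obj, cfg, origin = rigid_transform()),
               "outside")
})

test_that("self-registration converges to a near-identity pose", {
  case <- generate_case(seed = 5, scale = 0)
  tree <- assign_importance(classify_subbranches(case$tree))
  res <- register_vessels(tree, case$centerline, case$geom)
  spacing_mm <- mean(case$geom$pixel_spacing)
  expect_lt(res$final_aadd, spacing_mm)     # within rasterization noise
  err <- reprojection_error(tree_points(tree), case$geom, res$pose,
                            rigid_transform(), res$center)
  expect_lt(err, 0.5)
})

test_that("a bounded in-bounds perturbation is recovered", {
  case <- generate_case(seed = 8, scale = 2 / 3)
  tree <- assign_importance(classify_subbranches(case$tree))
  res <- register_vessels(tree, case$centerline, case$geom)
  err <- reprojection_error(tree_points(tree), case$geom, res$pose,
                            case$true_pose, res$center)
  expect_lt(err, 1.5)
  expect_true(all(diff(res$trace$aadd) <= 1e-12))
  expect_lte(res$final_aadd, res$trace$aadd[1])
})

test_that("map-based AADD tracks the exact nearest-pixel score within the chamfer bound", {
  case <- generate_case(seed = 2, scale = 1 / 3)
  tree <- assign_importance(classify_subbranches(case$tree))
  pts <- tree_points(tree)
  alpha <- tree$points$alpha
  geom <- case$geom
  spacing <- mean(geom$pixel_spacing)
  map <- build_local_distance_map(case$mask, 13 / spacing)
  pose <- rigid_transform(t = c(2, -1, 0), r = c(1, 0, -1))
  score_map <- aadd(pts, alpha, geom, pose, map, colMeans(pts))
  # brute force: exact nearest centerline pixel per projected point, capped
  proj <- project_points(pts, geom, pose, colMeans(pts))
  d_exact <- vesselreg:::nearest_mask_dist(cbind(proj$x, proj$y), case$mask)
  score_exact <- mean(alpha * pmin(d_exact, 13 / spacing) * spacing)
  # chamfer overestimates Euclidean by at most ~8.3%, plus rounding error
  expect_lt(abs(score_map - score_exact) / score_exact, 0.09 + 0.05)
})

test_that("tidy and glance summarize registration results", {
  case <- generate_case(seed = 5, scale = 0)
  tree <- assign_importance(classify_subbranches(case$tree))
  res <- register_vessels(tree, case$centerline, case$geom)
  td <- tidy(res)
  expect_equal(td$term, c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz"))
  expect_true(all(abs(td$estimate[1:3] - res$initial_pose$t) <= 13 + 1e-9))
  gl <- glance(res)
  expect_equal(gl$final_aadd, res$final_aadd)
  expect_true(gl$n_eval > 0)
})
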