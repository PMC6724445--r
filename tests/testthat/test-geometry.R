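test_that("intrinsic matrix encodes focal length times pixel density", {
  K <- intrinsic_matrix(simple_geometry(sid = 1000, sod = 700, spacing = 0.25))
  expect_equal(diag(K), c(4000, 4000, 1))
  expect_equal(K[1, 3], 256)
  expect_equal(K[2, 3], 256)

  # clinical case: sid 990 mm at 0.244 mm/px
  K2 <- intrinsic_matrix(simple_geometry(sid = 990, sod = 649.23,
                                         spacing = 0.244))
  expect_equal(K2[1, 1], 990 / 0.244, tolerance = 1e-12)
  expect_equal(round(K2[1, 1], 1), 4057.4)

  # anisotropic spacing: halving the column spacing doubles the x focal term
  K3 <- intrinsic_matrix(simple_geometry(spacing = c(0.4, 0.2)))
  expect_equal(K3[1, 1], 2 * K3[2, 2])
})

test_that("extrinsics are proper rotations that place the isocenter on the axis", {
  g0 <- simple_geometry()
  ext <- extrinsic_from_angles(g0)
  expect_equal(ext$R %*% t(ext$R), diag(3), tolerance = 1e-12)
  expect_equal(det(ext$R), 1, tolerance = 1e-12)
  # the isocenter maps to (0, 0, sod) in the camera frame
  expect_equal(as.numeric(ext$R %*% c(0, 0, 0) + ext$t), c(0, 0, 700))

  # pure primary rotation of 90 deg turns the patient x axis into the view axis
  g90 <- carm_geometry(90, 0, 1000, 700, 0.25)
  e90 <- extrinsic_from_angles(g90)
  expect_equal(as.numeric(e90$R %*% c(1, 0, 0)), c(0, 0, 1), tolerance = 1e-12)

  for (seed in 1:5) {
    set.seed(seed)
    g <- carm_geometry(runif(1, -90, 90), runif(1, -45, 45), 1100, 750, 0.28)
    R <- extrinsic_from_angles(g)$R
    expect_equal(R %*% t(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("the central ray projects to the principal point", {
  for (angles in list(c(0, 0), c(30, -20), c(-38, 45))) {
    g <- carm_geometry(angles[1], angles[2], 1050, 720, 0.28,
                       principal_point = c(256, 256))
    p <- project_points(matrix(0, 1, 3), g, rigid_transform(), center = c(0, 0, 0))
    expect_equal(c(p$x, p$y), c(256, 256), tolerance = 1e-9)
    expect_equal(p$depth, 720, tolerance = 1e-9)
  }
})

test_that("isocenter-plane magnification equals sid/sod (similar triangles)", {
  g <- simple_geometry(sid = 1000, sod = 700, spacing = 0.25)
  # 10 mm perpendicular offset at the isocenter plane
  p_pat <- patient_from_camera(c(10, 0, 700), g)
  p <- project_points(rbind(p_pat), g, rigid_transform(), center = c(0, 0, 0))
  expect_equal(unname(p$x - 256), 10 * (1000 / 700) / 0.25, tolerance = 1e-9)
  expect_equal(unname(p$y - 256), 0, tolerance = 1e-9)
})

test_that("perspective projection preserves rays and collinearity", {
  g <- carm_geometry(25, -15, 1100, 730, 0.27)
  cam <- c(12, -8, 500)
  two <- rbind(patient_from_camera(cam, g), patient_from_camera(2 * cam, g))
  p <- project_points(two, g, rigid_transform(), center = c(0, 0, 0))
  expect_equal(p$x[1], p$x[2], tolerance = 1e-9)
  expect_equal(p$y[1], p$y[2], tolerance = 1e-9)

  # three collinear points stay collinear within 1e-6 px
  a <- c(5, 3, -2); b <- c(-4, 8, 6)
  pts <- rbind(a, (a + b) / 2, b)
  pr <- project_points(pts, g, rigid_transform(), center = c(0, 0, 0))
  v1 <- c(pr$x[2] - pr$x[1], pr$y[2] - pr$y[1])
  v2 <- c(pr$x[3] - pr$x[1], pr$y[3] - pr$y[1])
  cross <- abs(v1[1] * v2[2] - v1[2] * v2[1]) / sqrt(sum(v2^2))
  expect_lt(cross, 1e-6)
})

test_that("projection is equivariant to rotations about the isocenter", {
  g <- carm_geometry(10, 20, 1000, 700, 0.25)
  set.seed(7)
  pts <- matrix(rnorm(30, sd = 20), 10, 3)
  rot <- rigid_transform(r = c(8, -5, 12))
  pre_rotated <- apply_rigid(pts, rot, center = c(0, 0, 0))
  a <- project_points(pre_rotated, g, rigid_transform(), center = c(0, 0, 0))
  b <- project_points(pts, g, rot, center = c(0, 0, 0))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("points behind the source are rejected", {
  g <- simple_geometry()
  behind <- patient_from_camera(c(0, 0, -10), g)
  expect_error(project_points(rbind(behind), g, rigid_transform(),
                              center = c(0, 0, 0)), "behind source")
})

test_that("rigid transforms are exact isometries with a working inverse", {
  set.seed(3)
  pts <- matrix(rnorm(15, sd = 30), 5, 3)
  expect_equal(apply_rigid(pts, rigid_transform()), pts)
  tr <- rigid_transform(t = c(1, 2, 3))
  expect_equal(apply_rigid(pts, tr), sweep(pts, 2, c(1, 2, 3), "+"))

  # 90 deg about z through the centroid of a 2-point set
  two <- rbind(c(1, 0, 0), c(-1, 0, 0))
  rot <- rigid_transform(r = c(0, 0, 90))
  out <- apply_rigid(two, rot)   # centroid (0,0,0)
  expect_equal(out, rbind(c(0, 1, 0), c(0, -1, 0)), tolerance = 1e-12)
  expect_equal(dist(out)[1], dist(two)[1], tolerance = 1e-12)

  pose <- rigid_transform(t = c(4, -2, 7), r = c(11, -9, 23))
  ctr <- c(3, 1, -2)
  inv <- invert_rigid(pose, ctr)
  roundtrip <- apply_rigid(apply_rigid(pts, pose, ctr), inv, ctr)
  expect_equal(roundtrip, pts, tolerance = 1e-9)
})

test_that("geometry construction validates physical parameters", {
  expect_warning(g <- carm_geometry(0, 0, -1000, 765, 0.258), "negative SID")
  expect_equal(g$sid, 1000)
  expect_error(carm_geometry(0, 0, 700, 1000, 0.25), "sid > sod")
  expect_error(carm_geometry(0, 0, 1000, 700, 0), "pixel_spacing")
})
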