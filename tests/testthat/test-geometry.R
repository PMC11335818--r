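test_that("project_marker reproduces the similar-triangles cases", {
  cam <- camera_model(1152, 986, focal_length = 1000,
                      principal_point = c(576, 493))
  mk <- marker_model(0.1)
  obs <- project_marker(pose_estimate(diag(3), c(0, 0, 1)), mk, cam)
  # 0.1 m x 1000 px / 1 m = 100 px square centred on the principal point
  expect_equal(obs$corners,
               rbind(c(526, 443), c(626, 443), c(626, 543), c(526, 543)),
               ignore_attr = TRUE, tolerance = 1e-12)

  # in-plane rotation commutes with projection about the principal point
  obs30 <- project_marker(pose_estimate(euler_to_matrix(30), c(0, 0, 1)),
                          mk, cam)
  th <- 30 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  centred <- sweep(obs$corners, 2, c(576, 493))
  expect_equal(obs30$corners,
               sweep(centred %*% t(Rz), 2, c(576, 493), `+`),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("project_marker matches the transform-then-divide oracle", {
  cam <- ceiling_camera()
  mk <- marker_model(0.1)
  R <- euler_to_matrix(25, 10, 5)
  tv <- c(0.1, -0.05, 1.2)
  obs <- project_marker(pose_estimate(R, tv), mk, cam)
  expect_lt(max(abs(obs$corners -
                      oracle_project(R, tv, 0.1, cam$focal_length,
                                     cam$principal_point))), 1e-9)
})

test_that("a corner behind the camera invalidates the observation", {
  cam <- ceiling_camera()
  mk <- marker_model(0.5)
  obs <- project_marker(pose_estimate(euler_to_matrix(0, 80), c(0, 0, 0.2)),
                        mk, cam)
  expect_false(obs$valid)
  expect_match(attr(obs, "reason"), "behind")
})

test_that("planar pose round-trips the projection (identity and random poses)", {
  cam <- ceiling_camera()
  mk <- marker_model(0.1)
  est <- estimate_planar_pose(
    project_marker(pose_estimate(diag(3), c(0, 0, 1)), mk, cam), mk, cam)
  expect_lt(abs(pose_to_head_yaw(est)), 1e-6)
  expect_lt(max(abs(est$translation - c(0, 0, 1))), 1e-6)

  est2 <- estimate_planar_pose(
    project_marker(pose_estimate(euler_to_matrix(37.5), c(0.05, 0.02, 1.1)),
                   mk, cam), mk, cam)
  expect_lt(abs(pose_to_head_yaw(est2) - 37.5), 1e-6)
  expect_lt(max(abs(est2$translation - c(0.05, 0.02, 1.1))), 1e-6)

  set.seed(11)
  for (i in 1:25) {
    R <- random_pose(60, 20)
    tv <- c(runif(2, -0.08, 0.08), runif(1, 0.8, 1.3))
    est <- estimate_planar_pose(
      project_marker(pose_estimate(R, tv), mk, cam), mk, cam)
    expect_lt(max(abs(est$rotation - R)), 1e-6)
    expect_lt(max(abs(est$translation - tv)), 1e-6)
    # decomposition output must be a proper rotation
    expect_lt(max(abs(crossprod(est$rotation) - diag(3))), 1e-9)
    expect_equal(det(est$rotation), 1, tolerance = 1e-9)
  }
})

test_that("yaw is invariant to marker distance and equivariant to image rotation", {
  cam <- ceiling_camera()
  mk <- marker_model(0.1)
  R <- euler_to_matrix(24)
  for (k in c(0.8, 1, 1.6)) {
    est <- estimate_planar_pose(
      project_marker(pose_estimate(R, k * c(0.02, 0.01, 1)), mk, cam),
      mk, cam)
    expect_lt(abs(pose_to_head_yaw(est) - 24), 1e-6)
  }
  # rotating the observed corners about the principal point adds that angle
  obs <- project_marker(pose_estimate(R, c(0, 0, 1)), mk, cam)
  th <- 13 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  obs_rot <- marker_observation(
    sweep(sweep(obs$corners, 2, cam$principal_point) %*% t(Rz), 2,
          cam$principal_point, `+`))
  est <- estimate_planar_pose(obs_rot, mk, cam)
  expect_lt(abs(pose_to_head_yaw(est) - (24 + 13)), 1e-6)
})

test_that("pose estimation flags or rejects degenerate input", {
  cam <- ceiling_camera()
  mk <- marker_model(0.1)
  bad <- marker_observation(rbind(c(0, 0), c(10, 10), c(20, 20), c(5, 30)))
  expect_error(estimate_planar_pose(bad, mk, cam), "collinear")
  expect_error(estimate_planar_pose(
    marker_observation(matrix(NA_real_, 4, 2), valid = FALSE), mk, cam),
    "invalid")
})

test_that("corner noise at large marker area leaves yaw accurate", {
  cam <- ceiling_camera()
  mk <- marker_model(0.1)
  set.seed(301)
  errs <- replicate(300, {
    yaw <- runif(1, -60, 60)
    pose <- pose_estimate(euler_to_matrix(yaw, runif(1, -2, 2),
                                          runif(1, -2, 2)),
                          c(runif(2, -0.05, 0.05), 1))
    obs <- project_marker(pose, mk, cam)
    area <- abs(sum(obs$corners[, 1] * obs$corners[c(2, 3, 4, 1), 2] -
                      obs$corners[c(2, 3, 4, 1), 1] * obs$corners[, 2])) / 2
    expect_gt(area, 80000)
    obs$corners <- obs$corners + rnorm(8, 0, 0.5)
    abs(matrix_to_euler(estimate_planar_pose(obs, mk, cam)$rotation)["yaw"] -
          yaw)
  })
  expect_lt(mean(errs), 0.1)
})

test_that("pose_to_head_yaw subtracts the reference and wraps", {
  p <- pose_estimate(euler_to_matrix(12), c(0, 0, 1))
  expect_equal(pose_to_head_yaw(p, 12), 0)
  expect_equal(pose_to_head_yaw(p, -58), 70)
  expect_equal(pose_to_head_yaw(pose_estimate(euler_to_matrix(-170),
                                              c(0, 0, 1)), 20), 170)
  expect_error(pose_to_head_yaw(pose_estimate(euler_to_matrix(0, 88),
                                              c(0, 0, 1))), "gimbal")
})

test_that("rotation vector conversions invert each other", {
  expect_equal(rotvec_to_matrix(c(0, 0, 0)), diag(3))
  expect_equal(as.numeric(rotvec_to_matrix(c(0, 0, pi / 2)) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:200) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2)) * runif(1, 1e-4, pi - 1e-3)
    expect_lt(max(abs(matrix_to_rotvec(rotvec_to_matrix(v)) - v)), 1e-10)
  }
})

test_that("Euler round trip away from gimbal lock", {
  set.seed(6)
  for (i in 1:50) {
    ang <- c(runif(1, -179, 179), runif(1, -85, 85), runif(1, -179, 179))
    eul <- matrix_to_euler(euler_to_matrix(ang[1], ang[2], ang[3]))
    expect_equal(unname(eul), ang, tolerance = 1e-9)
  }
})

test_that("camera model enforces its invariants", {
  expect_error(camera_model(1088, 1080), "focal_length")
  expect_error(camera_model(100, 100, focal_length = 50,
                            principal_point = c(200, 50)), "principal point")
  expect_error(camera_model(1088, 1080, focal_length = 100,
                            fov_horizontal = 82), "inconsistent")
  cam <- camera_model(1088, 1080, fov_horizontal = 82)
  expect_equal(cam$focal_length, (1088 / 2) / tan(41 * pi / 180))
})
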