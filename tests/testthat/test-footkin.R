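test_that("JCS decomposition inverts composition over the working range", {
  set.seed(11)
  err <- 0
  for (i in 1:300) {
    a <- runif(3, -60, 60)
    R <- jcs_compose(a[1], a[2], a[3])
    d <- jcs_angles(diag(3), R)
    err <- max(err, max(abs(unname(d) - a)))
  }
  expect_lt(err, 1e-6)
})

test_that("single-axis and identity rotations decompose as expected", {
  expect_equal(unname(jcs_angles(diag(3), diag(3))), c(0, 0, 0))
  d <- jcs_angles(diag(3), rot_z(10))
  expect_equal(unname(d), c(10, 0, 0), tolerance = 1e-12)
  d <- jcs_angles(diag(3), rot_x(-7) )
  expect_equal(unname(d)[2], -7, tolerance = 1e-12)
  # proximal frame is respected: rotating both segments together changes nothing
  Q <- rot_y(33) %*% rot_x(12)
  d2 <- jcs_angles(Q, Q %*% rot_z(10))
  expect_equal(unname(d2), c(10, 0, 0), tolerance = 1e-9)
})

test_that("angles are invariant under a common rigid lab-frame transform", {
  set.seed(12)
  for (i in 1:20) {
    a <- runif(3, -50, 50)
    Rp <- rot_y(runif(1, -40, 40)) %*% rot_z(runif(1, -40, 40))
    Rd <- Rp %*% jcs_compose(a[1], a[2], a[3])
    Q <- rot_x(runif(1, -80, 80)) %*% rot_y(runif(1, -80, 80))
    expect_equal(unname(jcs_angles(Q %*% Rp, Q %*% Rd)),
                 unname(jcs_angles(Rp, Rd)), tolerance = 1e-9)
  }
})

test_that("gimbal proximity is flagged", {
  d <- jcs_angles(diag(3), jcs_compose(5, 89.5, 10))
  expect_true(isTRUE(attr(d, "gimbal")))
  expect_error(jcs_angles(diag(3), matrix(1, 3, 3)), "orthonormal")
})

test_that("pose synthesis and JCS decomposition round-trip on smooth programs", {
  set.seed(13)
  worst <- 0
  for (rep in 1:15) {
    pr <- random_programs()
    kin <- synth_segment_poses(pr, rate = 200, duration = 0.25)
    ang <- trial_kinematics(list(segment_poses = kin$poses, markers = kin$markers))
    tau <- kin$tau
    for (j in c("sha_cal", "cal_mid", "mid_met", "met_hal")) {
      for (pl in c("sagittal", "frontal", "transverse")) {
        got <- ang[, paste0(j, ".", pl)]
        want <- pr[[j]][[pl]](tau)
        worst <- max(worst, max(abs(got - want)))
      }
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("pose synthesis rejects gimbal-proximal frontal programs", {
  pr <- random_programs()
  pr$sha_cal$frontal <- program_constant(95)
  expect_error(suppressWarnings(synth_segment_poses(pr, 200, 0.25)), "gimbal")
})

test_that("arch apex angle matches vector geometry and is isometry-invariant", {
  # apex between the endpoints: flat-arch limit
  expect_equal(mla_angle(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)), 180)
  a <- mla_angle(c(0, 0, 0), c(5, 3, 0), c(10, 0, 0))
  expect_equal(a, 2 * atan(5 / 3) * 180 / pi, tolerance = 1e-12)
  # rigid transform of the triad
  Q <- rot_z(37) %*% rot_x(-22)
  t0 <- c(4, -7, 2)
  a2 <- mla_angle(Q %*% c(0, 0, 0) + t0, Q %*% c(5, 3, 0) + t0,
                  Q %*% c(10, 0, 0) + t0)
  expect_equal(a2, a, tolerance = 1e-10)
  expect_error(mla_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("metatarsal inclination is signed head-down positive", {
  expect_equal(metatarsal_inclination(c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(metatarsal_inclination(c(0, 0, 0), c(1, -1, 0)), 45,
               tolerance = 1e-12)
  expect_equal(metatarsal_inclination(c(0, 0, 0), c(1, 1, 0)), -45,
               tolerance = 1e-12)
  # translation invariance
  expect_equal(metatarsal_inclination(c(3, 2, 1), c(4, 1, 1)), 45,
               tolerance = 1e-12)
  expect_error(metatarsal_inclination(c(1, 1, 1), c(1, 1, 1)), "zero-length")
})

test_that("transverse divergence is the signed ground-plane angle", {
  expect_equal(metatarsal_divergence(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(abs(metatarsal_divergence(c(1, 0, 0), c(0, 0, 1))), 90)
  # vertical components are projected out; sign follows the right-hand rule
  a <- c(1, 0.5, 0.2); b <- c(0.7, -0.3, 0.9)
  pa <- a * c(1, 0, 1); pb <- b * c(1, 0, 1)
  want <- atan2(pa[3] * pb[1] - pa[1] * pb[3], sum(pa * pb)) * 180 / pi
  expect_equal(metatarsal_divergence(a, b), want, tolerance = 1e-9)
  expect_error(metatarsal_divergence(c(0, 1, 0), c(1, 0, 0)), "projection")
})

test_that("marker-triad pose adapter yields orthonormal right-handed frames", {
  set.seed(14)
  for (i in 1:10) {
    o <- rnorm(3); a <- o + rnorm(3); b <- o + rnorm(3)
    p <- markers_to_pose(o, a, b)
    expect_equal(crossprod(p$R), diag(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(det(p$R), 1, tolerance = 1e-12)
  }
  expect_error(markers_to_pose(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})
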