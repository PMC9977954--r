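# axis-aligned anisotropic point cloud with analytically known PCs
ellipsoid_points <- function() {
  rbind(c(3, 0, 0), c(-3, 0, 0), c(2, 0, 0), c(-2, 0, 0),
        c(0, 2, 0), c(0, -2, 0), c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1))
}

test_that("principal frames align with analytic axes and follow sign conventions", {
  pts <- ellipsoid_points()
  fr <- principal_frame(pts, nose_centroid = c(10, 0, 0),
                        reference = c(0, 1, 0))
  expect_equal(abs(fr$axes[, "longitudinal"]), c(1, 0, 0), tolerance = 1e-6)
  expect_gt(fr$axes[1, "longitudinal"], 0)
  expect_gt(fr$axes[2, "vertical"], 0)
  # right-handed: longitudinal x vertical = transverse
  cr <- c(fr$axes[2, 1] * fr$axes[3, 2] - fr$axes[3, 1] * fr$axes[2, 2],
          fr$axes[3, 1] * fr$axes[1, 2] - fr$axes[1, 1] * fr$axes[3, 2],
          fr$axes[1, 1] * fr$axes[2, 2] - fr$axes[2, 1] * fr$axes[1, 2])
  expect_equal(unname(fr$axes[, "transverse"]), unname(cr),
               tolerance = 1e-10)

  # nose on the -x side flips longitudinal and transverse, keeps handedness
  fr2 <- principal_frame(pts, nose_centroid = c(-10, 0, 0),
                         reference = c(0, 1, 0))
  expect_equal(fr2$axes[, "longitudinal"], -fr$axes[, "longitudinal"],
               tolerance = 1e-10)
  expect_equal(fr2$axes[, "vertical"], fr$axes[, "vertical"],
               tolerance = 1e-10)
  expect_equal(fr2$axes[, "transverse"], -fr$axes[, "transverse"],
               tolerance = 1e-10)
  expect_equal(det(fr2$axes), 1, tolerance = 1e-10)
})

test_that("principal frames are equivariant under proper rotations", {
  pts <- ellipsoid_points()
  fr <- principal_frame(pts, c(10, 0, 0), c(0, 1, 0))
  R <- axis_rotation(c(1, 2, 3), 37)
  fr_rot <- principal_frame(pts %*% t(R), as.numeric(R %*% c(10, 0, 0)),
                            as.numeric(R %*% c(0, 1, 0)))
  expect_equal(fr_rot$axes, R %*% fr$axes, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate point sets raise errors and near-ties warn", {
  line <- cbind(1:10, 0, 0)
  expect_error(principal_frame(line, c(1, 0, 0)), "degenerate")
  sym <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 0.2), c(0, 0, -0.2))
  expect_warning(principal_frame(sym, c(10, 0, 0), c(0, 1, 0)), "near-tied")
})

test_that("relative rotations solve the frame alignment exactly", {
  pts <- ellipsoid_points()
  fr <- principal_frame(pts, c(10, 0, 0), c(0, 1, 0))
  expect_equal(relative_rotation(fr, fr), diag(3), tolerance = 1e-10)
  # arrestin frame yawed by 30 degrees about the shared vertical axis
  Rz <- axis_rotation(c(0, 1, 0), -30)  # vertical here is the y axis
  fr_y <- list(axes = Rz %*% fr$axes)
  class(fr_y) <- "xl_frame"
  R <- relative_rotation(fr, fr_y)
  expect_equal(det(R), 1, tolerance = 1e-10)
  # inverse symmetry
  expect_equal(relative_rotation(fr_y, fr), t(R), tolerance = 1e-10)
  expect_error(relative_rotation(diag(c(1, 1, 2)), diag(3)), "rotation")
})

test_that("pitch/roll/yaw formulas invert the rotation construction", {
  expect_equal(unclass(euler_angles(diag(3)))[1:3],
               c(pitch = 0, roll = 0, yaw = 0))
  # pure yaw
  ang <- euler_angles(rotation_from_angles(0, 0, 25))
  expect_equal(unname(ang[1:3]), c(0, 0, 25), tolerance = 1e-10)
  # full round trip
  ang2 <- euler_angles(rotation_from_angles(13, -17, 25))
  expect_equal(unname(ang2[1:3]), c(13, -17, 25), tolerance = 1e-9)
  # ranges
  set.seed(17)
  for (i in 1:25) {
    tr <- c(runif(1, -89, 89), runif(1, -179, 179), runif(1, -179, 179))
    back <- euler_angles(rotation_from_angles(tr[1], tr[2], tr[3]))
    expect_equal(unname(back[1:3]), tr, tolerance = 1e-9)
  }
  # gimbal lock flagged, roll folded to zero
  g <- euler_angles(rotation_from_angles(90, 30, 10))
  expect_true(attr(g, "gimbal"))
  expect_equal(unname(g["roll"]), 0)
})

test_that("static ensembles give constant angles and zero RMSD", {
  toy <- make_toy_complex(seed = 51)
  tr <- simulate_trajectory(toy$receptor, toy$mobile,
                            angular_sd = c(0, 0, 0), translation_sd = 0,
                            n_frames = 5, seed = 1)
  ori <- ensemble_orientation(tr$ensemble, "R", "A",
                              tr$receptor_nose, tr$arrestin_nose)
  expect_equal(ori$rmsd_A, rep(0, 5), tolerance = 1e-10)
  expect_equal(max(abs(diff(ori$yaw_deg))), 0, tolerance = 1e-10)
  expect_equal(unname(attr(ori, "max_deviation")), c(0, 0, 0),
               tolerance = 1e-10)
})

test_that("reversing the frame order reverses the orientation trace", {
  toy <- make_toy_complex(seed = 52)
  tr <- simulate_trajectory(toy$receptor, toy$mobile, n_frames = 6, seed = 2)
  ens <- tr$ensemble
  rev_ens <- ens
  rev_ens$xyz <- ens$xyz[, , 6:1]
  o1 <- ensemble_orientation(ens, "R", "A", tr$receptor_nose,
                             tr$arrestin_nose)
  o2 <- ensemble_orientation(rev_ens, "R", "A", tr$receptor_nose,
                             tr$arrestin_nose)
  expect_equal(o2$yaw_deg, rev(o1$yaw_deg), tolerance = 1e-10)
  expect_equal(o2$pitch_deg, rev(o1$pitch_deg), tolerance = 1e-10)
})

test_that("distance traces match brute-force statistics and analytic fractions", {
  # single frame: all stats equal the static distance
  st <- planted_distance_complex(c(7.3, 12.5))
  ens1 <- list(topology = st,
               xyz = array(as.matrix(st$atoms[, c("x", "y", "z")]),
                           c(nrow(st$atoms), 3, 1)))
  class(ens1) <- "xl_ensemble"
  pairs <- list(list(residue_ref("R", 1), residue_ref("A", 1)),
                list(residue_ref("R", 2), residue_ref("A", 2)))
  tr1 <- distance_trace(ens1, pairs)
  expect_equal(tr1$min_A, c(7.3, 12.5))
  expect_equal(tr1$median_A, tr1$max_A)
  expect_equal(tr1$ever_within_10.2, c(TRUE, FALSE))

  # sinusoidal distance 13 + 5 sin(theta): fraction below 15 has a closed form
  n <- 2000
  theta <- 2 * pi * (seq_len(n) - 1) / n
  dists <- 13 + 5 * sin(theta)
  base <- planted_distance_complex(c(8))
  xyz <- array(rep(as.matrix(base$atoms[, c("x", "y", "z")]), n),
               c(nrow(base$atoms), 3, n))
  xyz[2, 1, ] <- dists   # move the mobile CB along x
  ens <- list(topology = base, xyz = xyz)
  class(ens) <- "xl_ensemble"
  tr <- distance_trace(ens, list(list(residue_ref("R", 1),
                                      residue_ref("A", 1))))
  expect_true(tr$ever_within_10.2)
  analytic <- (pi + 2 * asin(0.4)) / (2 * pi)
  expect_equal(tr$frac_within_15, analytic, tolerance = 0.01)
  # quartiles equal a brute-force sort of the per-frame distances
  expect_equal(tr$q25_A, unname(quantile(dists, 0.25)), tolerance = 1e-12)
  expect_equal(tr$median_A, median(dists), tolerance = 1e-12)
  expect_equal(tr$q75_A, unname(quantile(dists, 0.75)), tolerance = 1e-12)
  expect_equal(tr$min_A, min(dists))
  expect_equal(tr$max_A, max(dists))
})

test_that("contact persistence counts frames below the cutoff", {
  base <- planted_distance_complex(c(3))
  xyz <- array(rep(as.matrix(base$atoms[, c("x", "y", "z")]), 4),
               c(nrow(base$atoms), 3, 4))
  xyz[2, 1, ] <- c(3, 3.5, 3.9, 8)   # contact in 3 of 4 frames at 4 A
  ens <- list(topology = base, xyz = xyz)
  class(ens) <- "xl_ensemble"
  pair <- list(list(residue_ref("R", 1), residue_ref("A", 1)))
  expect_equal(contact_persistence(ens, pair)$persistence, 0.75)
  expect_equal(contact_persistence(ens, pair, cutoff = 0)$persistence, 0)
})

test_that("any-of-group persistence dominates each single pair", {
  toy <- make_toy_complex(seed = 53)
  tr <- simulate_trajectory(toy$receptor, toy$mobile, n_frames = 15,
                            seed = 3)
  pairs <- lapply(1:3, function(i)
    list(residue_ref("R", toy$restraints$receptor_resno[i]),
         residue_ref("A", toy$restraints$arrestin_resno[i])))
  res <- contact_persistence(tr$ensemble, pairs, cutoff = 8, group = TRUE)
  expect_gte(attr(res, "any_of_group"), max(res$persistence))
})
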