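test_that("kabsch alignment is exact for rigid transforms and optimal under noise", {
  fr <- helix_frame()
  al0 <- kabsch_align(fr, fr, 1:12)
  expect_equal(al0$rotation, diag(3), tolerance = 1e-12)
  expect_lt(al0$rmsd, 1e-12)

  moved <- fr
  moved$coords <- fr$coords %*% t(rot_z(30)) + matrix(c(1, 2, 3), 12, 3, byrow = TRUE)
  al <- kabsch_align(moved, fr, 1:12)
  expect_lt(al$rmsd, 1e-10)
  expect_equal(det(al$rotation), 1, tolerance = 1e-10)

  # noisy transform: result at most as large as a brute-force rotation grid
  noisy <- fr
  noisy$coords <- withr::with_seed(2, fr$coords %*% t(rot_z(47)) +
                                     matrix(stats::rnorm(36, 0, 0.3), 12, 3))
  al2 <- kabsch_align(noisy, fr, 1:12)
  rot_x <- function(deg) {
    a <- deg * pi / 180
    matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  }
  best <- Inf
  Bc <- sweep(fr$coords, 2, colMeans(fr$coords))
  Ac <- sweep(noisy$coords, 2, colMeans(noisy$coords))
  for (a in seq(-180, 174, by = 6)) for (b in seq(0, 180, by = 9)) {
    for (g in seq(-180, 174, by = 9)) {
      R <- rot_z(g) %*% rot_x(b) %*% rot_z(a)
      best <- min(best, sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2))))
    }
  }
  expect_lte(al2$rmsd, best + 1e-12)

  line <- structure_frame(cbind(1:5, 0, 0), rep("CA", 5), 1:5)
  expect_error(kabsch_align(line, line, 1:5), "collinear")
})

test_that("distance_z measures axial translation and ignores axial rotation", {
  fr <- helix_frame()
  expect_equal(distance_z(fr, fr, 1:12, axis = c(0, 0, 1)), 0)
  shifted <- fr
  shifted$coords[, 3] <- shifted$coords[, 3] + 2
  expect_equal(distance_z(shifted, fr, 1:12, axis = c(0, 0, 1)), 2,
               tolerance = 1e-12)
  # default axis is the principal inertial axis (nearly z for this helix)
  expect_equal(distance_z(shifted, fr, 1:12), 2, tolerance = 1e-2)
  spun <- fr
  cm <- colMeans(fr$coords)
  spun$coords <- sweep(sweep(fr$coords, 2, cm) %*% t(rot_z(75)), 2, cm, "+")
  expect_lt(abs(distance_z(spun, fr, 1:12, axis = c(0, 0, 1))), 1e-10)
  expect_error(distance_z(fr, fr, integer(0)), "empty")
})

test_that("spin_angle recovers constructed rotations and matches a grid scan", {
  fr <- helix_frame()
  expect_equal(spin_angle(fr, fr, 1:12, axis = c(0, 0, 1)), 0)
  rot <- fr
  rot$coords <- fr$coords %*% t(rot_z(-60))
  expect_equal(spin_angle(rot, fr, 1:12, axis = c(0, 0, 1)), -60,
               tolerance = 1e-8)
  # antisymmetry for small rotations
  small <- fr
  small$coords <- fr$coords %*% t(rot_z(8.5))
  expect_equal(spin_angle(small, fr, 1:12, axis = c(0, 0, 1)),
               -spin_angle(fr, small, 1:12, axis = c(0, 0, 1)),
               tolerance = 1e-8)
  # closed form equals the argmin of a 0.01-degree RMSD scan
  noisy <- fr
  noisy$coords <- withr::with_seed(5, fr$coords %*% t(rot_z(23.4)) +
                                     matrix(stats::rnorm(36, 0, 0.1), 12, 3))
  sa <- spin_angle(noisy, fr, 1:12, axis = c(0, 0, 1))
  grid <- seq(sa - 2, sa + 2, by = 0.01)
  w <- fr$mass
  Ac <- sweep(fr$coords, 2, colMeans(fr$coords))
  Bc <- sweep(noisy$coords, 2, colMeans(noisy$coords))
  rmsd <- vapply(grid, function(a)
    sum(w * rowSums((Ac %*% t(rot_z(a)) - Bc)^2)), numeric(1))
  expect_lt(abs(grid[which.min(rmsd)] - sa), 0.011)

  online <- structure_frame(cbind(0, 0, 1:5), rep("CA", 5), 1:5)
  expect_error(spin_angle(online, online, 1:5, axis = c(0, 0, 1)), "axis")
})

test_that("displacement charge follows the Q-route definition", {
  fq <- structure_frame(matrix(0, 1, 3), "X", 1, charge = 1,
                        box_length_z = 80, unwrapped_z = 0)
  expect_equal(displacement_charge(fq), 0.5)
  lo <- fq; lo$unwrapped_z <- -40
  hi <- fq; hi$unwrapped_z <- 40
  expect_equal(displacement_charge(hi) - displacement_charge(lo), 1)
  # electroneutral system is invariant under uniform shifts
  fn <- structure_frame(matrix(0, 2, 3), c("X", "Y"), 1:2,
                        charge = c(1, -1), box_length_z = 60,
                        unwrapped_z = c(3, -7))
  shifted <- fn; shifted$unwrapped_z <- fn$unwrapped_z + 13.7
  expect_equal(displacement_charge(fn), displacement_charge(shifted),
               tolerance = 1e-12)
  # linearity: shifting all atoms changes Qd by sum(q) * dz / Lz exactly
  fc <- structure_frame(matrix(0, 2, 3), c("X", "Y"), 1:2,
                        charge = c(1, 0.5), box_length_z = 60,
                        unwrapped_z = c(3, -7))
  sh <- fc; sh$unwrapped_z <- fc$unwrapped_z + 6
  expect_equal(displacement_charge(sh) - displacement_charge(fc),
               1.5 * 6 / 60, tolerance = 1e-12)
  bad <- fq; bad$unwrapped_z <- NULL
  expect_error(displacement_charge(bad), "unwrapped")
})

test_that("salt-bridge distances handle atoms, groups, and the 60-pair list", {
  fr <- structure_frame(rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 2), c(0, 0, 0)),
                        c("CZ", "CG", "O1", "O2"), c(1, 2, 3, 3))
  d <- salt_bridge_distances(fr, list(list(c(1), c(2))))
  expect_equal(unname(d), 5)
  # atom vs 2-atom group: COM of two equal-mass O at z = 0 and 2 is z = 1
  d2 <- salt_bridge_distances(fr, list(list(c(1), c(3, 4))))
  expect_equal(unname(d2), 1, tolerance = 1e-12)

  frv <- synthetic_vsd_frame()
  pairs <- committor_distance_pairs()
  expect_length(pairs, 60)
  dd <- salt_bridge_distances(frv, pairs)
  expect_length(dd, 60)
  expect_true(all(dd > 0))
  expect_error(
    salt_bridge_distances(frv, list(list(list(resid = 226, atom = "XX"),
                                         list(resid = 129, atom = "CG")))),
    "available")
})

test_that("hydrogen bonds respect distance and angle cutoffs monotonically", {
  mk <- function(da, hpos) {
    structure_frame(rbind(c(0, 0, 0), hpos, c(da, 0, 0)),
                    c("N", "H", "O"), c(1, 1, 2))
  }
  # collinear D-H-A at 2.9 A
  hb <- hydrogen_bonds(mk(2.9, c(1, 0, 0)), cbind(1, 2), 3)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$angle, 180)
  # distance cutoff
  expect_equal(nrow(hydrogen_bonds(mk(3.6, c(1, 0, 0)), cbind(1, 2), 3)), 0)
  # bent D-H-A geometry (angle well below 120 degrees) fails the cutoff
  bent <- structure_frame(rbind(c(0, 0, 0), c(0, 1, 0), c(2.9, 0, 0)),
                          c("N", "H", "O"), c(1, 1, 2))
  expect_equal(nrow(hydrogen_bonds(bent, cbind(1, 2), 3)), 0)
  # tightening criteria can only shrink the set
  frset <- withr::with_seed(8, structure_frame(matrix(stats::rnorm(60), 20, 3),
                                               rep(c("N", "H", "O", "C"), 5), rep(1:5, each = 4)))
  don <- cbind(which(frset$atom_name == "N"), which(frset$atom_name == "H"))
  acc <- which(frset$atom_name == "O")
  loose <- hydrogen_bonds(frset, don, acc, hbond_criteria(4.5, 90))
  tight <- hydrogen_bonds(frset, don, acc, hbond_criteria(3.0, 140))
  expect_lte(nrow(tight), nrow(loose))
  key <- function(h) paste(h$donor, h$acceptor)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("CVs are invariant to rigid motion of the whole system after realignment", {
  fr <- helix_frame()
  sel <- 1:12
  d0 <- distance_z(fr, fr, sel, axis = c(0, 0, 1))
  # arbitrary rigid motion of the whole system
  R <- rot_z(37) %*% matrix(c(1, 0, 0, 0, cos(0.4), -sin(0.4), 0, sin(0.4), cos(0.4)), 3, byrow = TRUE)
  moved <- fr
  moved$coords <- fr$coords %*% t(R) + matrix(c(5, -3, 2), 12, 3, byrow = TRUE)
  re <- kabsch_align(moved, fr, sel)$frame
  expect_lt(abs(distance_z(re, fr, sel, axis = c(0, 0, 1)) - d0), 1e-6)
  expect_lt(abs(spin_angle(re, fr, sel, axis = c(0, 0, 1))), 1e-6)
})
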