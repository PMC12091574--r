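test_that("orientation angles match hand constructions", {
  # water at origin, dipole along +z (H's straddling +z), solute along +z
  o <- c(0, 0, 0)
  h1 <- c(0.6, 0, 0.75); h2 <- c(-0.6, 0, 0.75)
  a <- orientation_angles(o, h1, h2, solute = c(0, 0, 5))
  expect_equal(a$theta, 0, tolerance = 1e-9)
  # solute +z, dipole +x, H-H along +y: theta 90, normal z cross x = y vs
  # H1->H2 = +y: chi 0
  h1b <- c(0.75, -0.6, 0); h2b <- c(0.75, 0.6, 0)
  b <- orientation_angles(o, h1b, h2b, solute = c(0, 0, 5))
  expect_equal(b$theta, 90, tolerance = 1e-9)
  expect_equal(b$chi, 0, tolerance = 1e-9)
  # degenerate: dipole parallel to solute vector flags the sample
  d <- orientation_angles(o, h1, h2, solute = c(0, 0, -5))
  expect_false(is.na(d$theta))
  expect_false(d$ok)
})

test_that("orientation angles are invariant under rigid rotation", {
  set.seed(20)
  o <- c(1, 2, 3)
  h1 <- o + c(0.6, 0, 0.75); h2 <- o + c(-0.6, 0, 0.75)
  sol <- c(4, -1, 2)
  ref <- orientation_angles(o, h1, h2, sol)
  for (i in 1:20) {
    R <- random_rotation_matrix()
    rot <- orientation_angles(drop(R %*% o), drop(R %*% h1), drop(R %*% h2),
                              drop(R %*% sol))
    expect_equal(rot$theta, ref$theta, tolerance = 1e-9)
    expect_equal(rot$chi, ref$chi, tolerance = 1e-9)
  }
})

test_that("rotational entropy recovers closed forms", {
  u <- gen_oriented_waters("uniform", n = 2e5, seed = 21)
  expect_lt(abs(rotational_entropy(u$theta, u$chi)$TS_rot), 0.02)
  h <- gen_oriented_waters("half_domain", n = 2e5, seed = 22)
  expect_equal(rotational_entropy(h$theta, h$chi)$TS_rot, -kB * 273 * log(2),
               tolerance = 0.03)
  s <- gen_oriented_waters("single_bin", n = 2e4, seed = 23, bin = c(5, 11))
  # all mass in one bin: the estimate is exact, no sampling error
  expect_equal(rotational_entropy(s$theta, s$chi)$TS_rot, s$ts_rot_true,
               tolerance = 1e-9)
  k <- gen_oriented_waters("concentrated", n = 2e5, seed = 24, kappa = 3)
  expect_equal(rotational_entropy(k$theta, k$chi)$TS_rot, k$ts_rot_true,
               tolerance = 0.02)
})

test_that("estimator bias on uniform samples is negative and shrinks with n", {
  bias <- vapply(c(1e3, 1e4, 1e5), function(n) {
    mean(vapply(1:3, function(s) {
      u <- gen_oriented_waters("uniform", n = n, seed = 100 + s)
      rotational_entropy(u$theta, u$chi, min_samples = 1)$TS_rot
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(bias <= 1e-6))
  expect_true(abs(bias[3]) < abs(bias[1]))
})

test_that("entropy computed on growing sample prefixes plateaus", {
  k <- gen_oriented_waters("concentrated", n = 2e5, seed = 25, kappa = 5)
  half <- rotational_entropy(k$theta[1:1e5], k$chi[1:1e5])$TS_rot
  full <- rotational_entropy(k$theta, k$chi)$TS_rot
  expect_lt(abs(full - half) / abs(full), 0.05)
})

test_that("entropy is invariant under rigid rotation of the whole system", {
  set.seed(26)
  # concentrated geometric samples: random rotations about the solute axis
  n <- 5000
  o <- matrix(0, n, 3)
  h1 <- matrix(NA_real_, n, 3); h2 <- matrix(NA_real_, n, 3)
  base1 <- c(0.6, 0.2, 0.72); base2 <- c(-0.6, 0.2, 0.72)
  for (i in 1:n) {
    R <- random_rotation_matrix()
    h1[i, ] <- drop(R %*% base1); h2[i, ] <- drop(R %*% base2)
  }
  sol <- matrix(rep(c(0, 0, 5), each = n), n, 3)
  a0 <- orientation_angles(o, h1, h2, sol)
  e0 <- rotational_entropy(a0$theta[a0$ok], a0$chi[a0$ok], min_samples = 1)$TS_rot
  Rg <- random_rotation_matrix()
  rot <- function(m) t(Rg %*% t(m))
  a1 <- orientation_angles(rot(o), rot(h1), rot(h2), rot(sol))
  e1 <- rotational_entropy(a1$theta[a1$ok], a1$chi[a1$ok], min_samples = 1)$TS_rot
  expect_equal(e0, e1, tolerance = 1e-9)
})

test_that("translational entropy recovers uniform, octant and Gaussian forms", {
  set.seed(27)
  cell <- rbind(c(0, 0, 0), c(1, 1, 1))
  pos <- matrix(runif(3e5), ncol = 3)
  expect_lt(abs(translational_entropy(pos, cell = cell)$TS_trans), 0.01)
  expect_equal(translational_entropy(pos / 2, cell = cell)$TS_trans,
               -kB * 273 * log(8), tolerance = 0.01)
  # isotropic Gaussian: discrete voxel entropy approximates the differential
  # closed form k_B T (1.5 ln(2 pi e sigma^2) - ln V) for fine-enough voxels
  sigma <- 1; Lc <- 10
  g <- matrix(rnorm(3e5, sd = sigma), ncol = 3)
  cellg <- rbind(rep(-Lc / 2, 3), rep(Lc / 2, 3))
  est <- translational_entropy(g, bins = c(20, 20, 20), cell = cellg)$TS_trans
  closed <- kB * 273 * (1.5 * log(2 * pi * exp(1) * sigma^2) - 3 * log(Lc))
  expect_equal(est, closed, tolerance = abs(closed) * 0.02)
})

test_that("entropy profile ranks frozen below free and recovers mixture order", {
  ibs <- gen_toy_ibs(n_frames = 60, n_free = 5, n_pinned = 2, seed = 28)
  gt <- ground_truth(ibs)
  pmap <- permute_trajectory(ibs)
  prof <- entropy_profile(ibs, pmap, labels = 1:7, solute_sites = gt$sites$og1,
                          min_samples = 1)
  expect_equal(sort(prof$label[1:2]), gt$pinned_labels)
  # mixture of concentration parameters: recovered entropy order matches
  mix <- gen_oriented_waters("mixture", n = 3e4, seed = 29, kappa = c(8, 2, 0))
  est <- vapply(mix$streams, function(s)
    rotational_entropy(s$theta, s$chi)$TS_rot, numeric(1))
  expect_equal(order(est), order(mix$ts_rot_true))
  expect_equal(est, mix$ts_rot_true, tolerance = 0.05)
})
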