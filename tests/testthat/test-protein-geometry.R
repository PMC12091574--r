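test_that("theta_S and theta_T match hand geometry and parallel cases", {
  tr <- make_toy_protein(n_thr = 3)
  lad <- thr_ladder(tr, 1:3)
  ca <- select_atoms(tr, name = "CA")
  # axis along x; CB -> OG1 along z: 90 degrees
  ts <- theta_S(tr, lad, axis_atoms = ca[c(1, 3)])
  expect_true(all(abs(ts$angle - 90) < 1e-9))
  tt <- theta_T(tr, lad)
  expect_true(all(abs(tt$angle - 90) < 1e-9))
  # hand geometry: tilt OG1 so CB -> OG1 = (1, 0, 1): 45 degrees to the x axis
  tr2 <- tr
  og1 <- select_atoms(tr2, name = "OG1", resid = 1)
  cb <- select_atoms(tr2, name = "CB", resid = 1)
  tr2$coords[og1, , 1] <- tr2$coords[cb, , 1] + c(1, 0, 1)
  ts2 <- theta_S(tr2, thr_ladder(tr2, 1:3), axis_atoms = ca[c(1, 3)])
  expect_equal(ts2$angle[ts2$resid == 1], 45, tolerance = 1e-9)
})

test_that("theta series are invariant under rigid rotation of the structure", {
  tr <- make_toy_protein(n_thr = 3, n_frames = 3, jitter = 0.2, seed = 60)
  lad <- thr_ladder(tr, 1:3)
  ca <- select_atoms(tr, name = "CA")
  ref_s <- theta_S(tr, lad, axis_atoms = ca[c(1, 3)])
  ref_t <- theta_T(tr, lad)
  set.seed(61)
  R <- random_rotation_matrix()
  tr2 <- tr
  for (f in 1:3) tr2$coords[, , f] <- tr$coords[, , f] %*% t(R)
  expect_equal(theta_S(tr2, lad, axis_atoms = ca[c(1, 3)])$angle, ref_s$angle,
               tolerance = 1e-9)
  expect_equal(theta_T(tr2, lad)$angle, ref_t$angle, tolerance = 1e-9)
})

test_that("side-chain RMSD is zero for the reference and rigid motions", {
  tr <- make_toy_protein(n_thr = 3, n_frames = 2)
  # frame 2 = rigidly moved frame 1
  set.seed(62)
  R <- random_rotation_matrix()
  tr$coords[, , 2] <- sweep(tr$coords[, , 1] %*% t(R), 2, c(3, -2, 1), "+")
  r <- sidechain_rmsd(tr, resids = 1:3)
  expect_true(all(abs(r$rmsd) < 1e-6))
})

test_that("a single displaced side-chain atom gives RMSD d/sqrt(m)", {
  tr <- make_toy_protein(n_thr = 3, n_frames = 2)
  og1 <- select_atoms(tr, name = "OG1", resid = 2)
  tr$coords[og1, , 2] <- tr$coords[og1, , 2] + c(0, 0, 0.8)
  r <- sidechain_rmsd(tr, resids = 2)
  # m = 2 side-chain heavy atoms (CB, OG1)
  expect_equal(r$rmsd[r$frame == 2], 0.8 / sqrt(2), tolerance = 1e-6)
  expect_equal(r$rmsd[r$frame == 1], 0)
})

test_that("ladder spacing reports static and jittered distances", {
  tr <- make_toy_protein(n_thr = 3, spacing = 6.9)
  lad <- thr_ladder(tr, 1:3)
  sp <- ladder_spacing(tr, lad, "intra_strand_TxT")
  expect_equal(sp$mean, 6.9, tolerance = 1e-9)
  # harmonic jitter of amplitude a << d: mean approaches d + O(a^2/d)
  trj <- make_toy_protein(n_thr = 3, spacing = 6.9, n_frames = 400,
                          jitter = 0.15, seed = 63)
  spj <- ladder_spacing(trj, thr_ladder(trj, 1:3), "intra_strand_TxT")
  # E[d] ~ d + 2 sigma^2 / d for isotropic jitter of both ends
  expect_equal(spj$mean, 6.9 + 2 * 0.15^2 / 6.9, tolerance = 0.01)
  # inter-strand mode pairs position-matched residues across ladders
  sp2 <- ladder_spacing(tr, lad, "inter_strand_ladder", ladder2 = lad)
  expect_equal(sp2$mean, 0)
})

test_that("stacking and Ser-Gly distances recover constructed distributions", {
  tr <- make_toy_protein(n_thr = 3, spacing = 5)
  cb <- select_atoms(tr, name = "CB")
  st <- stacking_distances(tr, cb)
  expect_equal(st$summary$mean, c(5, 5), tolerance = 1e-9)
  expect_error(stacking_distances(tr, cb[1]), "at least 2")
  expect_error(stacking_distances(tr, c(cb[1], cb[1])), "identical atoms")
  # Gaussian spread: moments recovered
  trg <- make_toy_protein(n_thr = 2, spacing = 5, n_frames = 500,
                          jitter = 0.2, seed = 64)
  cbg <- select_atoms(trg, name = "CB")
  stg <- stacking_distances(trg, cbg)
  expect_equal(stg$summary$mean, 5 + 2 * 0.2^2 / 5, tolerance = 0.03)
  # jitter sd 0.2 on both ends: distance sd ~ sqrt(2) * 0.2
  expect_equal(stg$summary$sd, sqrt(2) * 0.2, tolerance = 0.05)
  og <- select_atoms(tr, name = "OG1", resid = 1)
  co <- select_atoms(tr, name = "C", resid = 2)
  sg <- ser_gly_distances(tr, og, co)
  expect_equal(nrow(sg$summary), 1)
  expect_true(sg$summary$iqr >= 0)
})
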