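test_that("MSD is zero for static particles and t^2 for ballistic motion", {
  tr <- make_water_box(matrix(runif(15, 2, 8), 5, 3), box_L = 10, n_frames = 6)
  m <- msd(tr, max_lag = 4)
  expect_equal(m$msd, rep(0, 4))
  # ballistic: x = v t, v = 1 A/ps along x
  nf <- 20
  pos <- array(0, c(nf, 3, 2))
  pos[, 1, ] <- (0:(nf - 1)) * 0.1  # dt = 0.1, v = 1
  attr(pos, "dt") <- 0.1
  mb <- msd(pos, max_lag = 10)
  expect_equal(mb$msd, mb$t^2, tolerance = 1e-12)
  expect_error(msd(pos, max_lag = 30), "below the trajectory length")
})

test_that("unwrapping recovers the Brownian generator's continuous paths", {
  br <- gen_brownian_box(D = 0.3, n_waters = 10, dt = 0.1, n_frames = 50,
                         box_L = 8, seed = 50)
  gt <- ground_truth(br)
  un <- unwrap_trajectory(br)
  for (w in c(1, 5, 10)) {
    path <- t(un[br$waters$O[w], , ])
    # unwrapped path matches ground truth up to the constant first-frame offset
    delta <- path - gt$unwrapped[, , w]
    expect_lt(max(abs(sweep(delta, 2, delta[1, ]))), 1e-9)
  }
})

test_that("Einstein relation: Brownian D recovered from the MSD slope", {
  br <- gen_brownian_box(D = 0.2, n_waters = 400, dt = 0.1, n_frames = 150,
                         seed = 51)
  m <- msd(br, max_lag = 40)
  expect_equal(msd_diffusion(m), 0.2, tolerance = 0.2 * 0.05)
})

test_that("permuted-label displacement never exceeds raw-label displacement", {
  br <- gen_brownian_box(D = 0.3, n_waters = 30, dt = 0.1, n_frames = 40,
                         box_L = 20, seed = 52)
  pmap <- permute_trajectory(br)
  # total squared min-image displacement from reference per frame
  expect_true(all(pmap$costs <= pmap$identity_costs + 1e-9))
  ref <- t(vapply(1:30, function(w) br$coords[br$waters$O[w], , 1], numeric(3)))
  f <- n_frames(br)
  raw <- mean(vapply(1:30, function(w)
    sum(min_image(br$coords[br$waters$O[w], , f] - ref[w, ], br$box[, , f])^2),
    numeric(1)))
  perm <- mean(vapply(1:30, function(w)
    sum(min_image(br$coords[br$waters$O[pmap$perm[f, w]], , f] - ref[w, ],
                  br$box[, , f])^2), numeric(1)))
  expect_lte(perm, raw + 1e-9)
})

test_that("survival curve obeys its limiting cases and monotonicity", {
  nf <- 40; nw <- 6
  # no exits
  stay <- survival_curve(matrix(TRUE, nf, nw), matrix(FALSE, nf, nw),
                         max_lag = 30, dt = 0.1)
  expect_true(all(stay$C == 1))
  # all teleport to product at the second frame
  prod <- matrix(TRUE, nf, nw); prod[1, ] <- FALSE
  react <- matrix(FALSE, nf, nw); react[1, ] <- TRUE
  gone <- survival_curve(react, prod, max_lag = 30, dt = 0.1)
  expect_equal(gone$C[gone$lag == 0], 1)
  expect_true(all(gone$C[gone$lag >= 1] == 0))
  # Poisson exits: C(t) matches exp(-k t); first-passage C is non-increasing
  ex <- gen_exchange_trajectory(k_exit = 0.04, n_waters = 300, dt = 0.1,
                                n_frames = 800, seed = 53)
  gt <- ground_truth(ex)
  sc <- survival_curve(gt$bound, !gt$bound, max_lag = 600, dt = 0.1,
                       origin_stride = 50)
  expect_true(all(diff(sc$C) <= 1e-12))
  expect_lt(max(abs(sc$C - exp(-0.04 * sc$t))), 0.05)
  expect_error(survival_curve(matrix(FALSE, 5, 2), matrix(FALSE, 5, 2), 3),
               "no reactant members")
})

test_that("first passage ignores transient recrossings; instantaneous does not", {
  # one water: reactant at frame 1, reaches product at frame 3, returns at 4
  react <- matrix(FALSE, 6, 1); react[1, 1] <- TRUE
  prod <- matrix(FALSE, 6, 1); prod[3, 1] <- TRUE
  fp <- survival_curve(react, prod, max_lag = 5, dt = 1)
  expect_equal(fp$C, c(1, 1, 0, 0, 0, 0))
  inst <- survival_curve(react, prod, max_lag = 5, dt = 1,
                         mode = "instantaneous")
  expect_equal(inst$C, c(1, 1, 0, 1, 1, 1))
})

test_that("bi-exponential fit recovers generating parameters and tau", {
  t <- seq(0, 400, by = 0.5)
  C <- 0.7 * exp(-t / 10) + 0.3 * exp(-t / 100)
  f <- fit_biexponential(t, C)
  expect_equal(f$C1, 0.7, tolerance = 0.01)
  expect_equal(f$tau1, 10, tolerance = 0.1)
  expect_equal(f$C2, 0.3, tolerance = 0.01)
  expect_equal(f$tau2, 100, tolerance = 1)
  expect_equal(f$tau, 37, tolerance = 0.37)
  expect_lte(f$tau1, f$tau2)
  expect_true(f$tau >= f$tau1 && f$tau <= f$tau2)
  # single exponential collapses to one effective timescale
  f2 <- fit_biexponential(t, exp(-t / 20))
  expect_equal(f2$tau, 20, tolerance = 0.2)
  expect_error(fit_biexponential(t, rep(0.5, length(t))), "no decay")
  expect_error(fit_biexponential(1:5, exp(-(1:5))), "at least 10 lag points")
})

test_that("tau is robust to 1% additive noise across seeded replicates", {
  t <- seq(0, 400, by = 0.5)
  C <- 0.7 * exp(-t / 10) + 0.3 * exp(-t / 100)
  set.seed(54)
  taus <- vapply(1:20, function(i)
    fit_biexponential(t, C + rnorm(length(t), sd = 0.01))$tau, numeric(1))
  expect_true(all(abs(taus - 37) / 37 < 0.05))
})

test_that("geometric SSP pipeline recovers the exchange generator's tau", {
  for (tau_true in c(10, 50)) {
    dt <- tau_true / 100               # keep k_exit * dt = 0.01
    ex <- gen_exchange_trajectory(k_exit = 1 / tau_true, n_waters = 200,
                                  dt = dt, n_frames = 600,
                                  seed = 55 + tau_true)
    gt <- ground_truth(ex)
    sc <- ssp_survival(ex, gt$hydroxyls, gt$ibs_sites, max_lag = 550,
                       origin_stride = 25)
    f <- fit_biexponential(sc)
    expect_equal(f$tau, tau_true, tolerance = tau_true * 0.1)
  }
})
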