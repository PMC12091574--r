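test_that("detector honors distance and angle thresholds", {
  # donor at origin with H along +x; acceptor placed on/off axis
  place <- function(acc) {
    o <- rbind(c(5, 5, 5), acc + c(5, 5, 5))
    tr <- make_water_box(o, box_L = 20)
    # overwrite H1 of donor to lie along +x
    tr$coords[tr$waters$H1[1], , 1] <- c(5.96, 5, 5)
    tr
  }
  donors <- function(tr) data.frame(O = tr$waters$O[1], H = tr$waters$H1[1])
  tr <- place(c(2.8, 0, 0))
  hb <- detect_hbonds(tr, 1, donors(tr), tr$waters$O[2])
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.8)
  expect_equal(hb$angle, 0, tolerance = 1e-9)
  tr2 <- place(c(3.6, 0, 0))
  expect_equal(nrow(detect_hbonds(tr2, 1, donors(tr2), tr2$waters$O[2])), 0)
  # deviation angle 32 degrees at r = 3.0: excluded at 30, included at 35
  acc <- 3.0 * c(cos(32 * pi / 180), sin(32 * pi / 180), 0)
  tr3 <- place(acc)
  expect_equal(nrow(detect_hbonds(tr3, 1, donors(tr3), tr3$waters$O[2],
                                  hbond_criterion(3.5, 30))), 0)
  expect_equal(nrow(detect_hbonds(tr3, 1, donors(tr3), tr3$waters$O[2],
                                  hbond_criterion(3.5, 35))), 1)
})

test_that("lattice waters have 4 bonds, isolated waters none", {
  lat <- gen_tetrahedral_lattice(n_cells = 2, jitter = 0)
  counts <- avg_hbonds_per_water(lat, labels = seq_len(n_waters(lat)))
  expect_true(all(counts == 4))
  iso <- make_water_box(matrix(c(5, 5, 5), 1, 3), box_L = 30)
  expect_equal(unname(avg_hbonds_per_water(iso, labels = 1)), 0)
})

test_that("detector matches the generator's independent brute-force count", {
  for (sd in c(0.15, 0.3)) {
    lat <- gen_tetrahedral_lattice(n_cells = 2, jitter = sd, n_frames = 2,
                                   seed = 31)
    gt <- ground_truth(lat)
    counts <- matrix(NA_real_, 2, n_waters(lat))
    for (f in 1:2) {
      tr1 <- lat; tr1$coords <- lat$coords[, , f, drop = FALSE]
      tr1$box <- lat$box[, , f, drop = FALSE]
      counts[f, ] <- avg_hbonds_per_water(tr1, labels = seq_len(n_waters(lat)))
    }
    expect_equal(unname(counts), unname(gt$hbond_counts * 1.0))
  }
})

test_that("H label swap and lattice-vector translation change nothing", {
  set.seed(32)
  tr <- make_water_box(matrix(runif(24, 0, 8), 8, 3), box_L = 8)
  base <- detect_hbonds(tr, 1, water_donors(tr), tr$waters$O)
  # swap H1/H2 identities
  tr2 <- tr
  tmp <- tr2$waters$H1; tr2$waters$H1 <- tr2$waters$H2; tr2$waters$H2 <- tmp
  sw <- detect_hbonds(tr2, 1, water_donors(tr2), tr2$waters$O)
  key <- function(d) sort(paste(d$donor_o, d$acceptor_o))
  expect_equal(key(sw), key(base))
  # translate one molecule by a lattice vector
  tr3 <- tr
  rows <- with(tr3$waters, c(O[3], H1[3], H2[3]))
  tr3$coords[rows, 1, 1] <- tr3$coords[rows, 1, 1] + 8
  mv <- detect_hbonds(tr3, 1, water_donors(tr3), tr3$waters$O)
  expect_equal(key(mv), key(base))
})

test_that("loosening the criterion never removes a detected bond", {
  set.seed(33)
  tr <- make_water_box(matrix(runif(36, 0, 9), 12, 3), box_L = 9)
  tight <- detect_hbonds(tr, 1, water_donors(tr), tr$waters$O,
                         hbond_criterion(3.0, 25))
  loose <- detect_hbonds(tr, 1, water_donors(tr), tr$waters$O,
                         hbond_criterion(3.5, 35))
  tight_keys <- paste(tight$h, tight$acceptor_o)
  loose_keys <- paste(loose$h, loose$acceptor_o)
  expect_true(all(tight_keys %in% loose_keys))
})

test_that("hydroxyl-bonded water selection follows occupancy ground truth", {
  ibs <- gen_toy_ibs(n_frames = 10, n_free = 6, n_pinned = 2, seed = 34)
  gt <- ground_truth(ibs)
  hyd <- list(O = gt$sites$og1, H = gt$sites$hg1)
  sel <- waters_hbonded_to_hydroxyls(ibs, hyd)
  expect_equal(sort(sel$label), gt$pinned_labels)
  # occupancy_min = 0 keeps every label ever bonded at least one frame
  sel0 <- waters_hbonded_to_hydroxyls(ibs, hyd, occupancy_min = 0)
  expect_true(all(gt$pinned_labels %in% sel0$label))
  # two-state exchanger: bound fraction per label is the generator's record
  ex <- gen_exchange_trajectory(k_exit = 0.05, n_waters = 30, dt = 0.1,
                                n_frames = 120, seed = 35)
  gte <- ground_truth(ex)
  sel2 <- waters_hbonded_to_hydroxyls(ex, gte$hydroxyls, occupancy_min = 0.5)
  expect_equal(sort(sel2$label), which(colMeans(gte$bound) >= 0.5))
  expect_error(waters_hbonded_to_hydroxyls(ex, list(O = integer(), H = integer())),
               "empty hydroxyl site set")
})

test_that("a donor without hydrogens is a hard error naming the atom", {
  tr <- make_water_box(matrix(c(2, 2, 2, 4, 2, 2), 2, 3, byrow = TRUE), 10)
  expect_error(detect_hbonds(tr, 1, data.frame(O = tr$waters$O[1], H = NA),
                             tr$waters$O[2]),
               "has no hydrogen")
})
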