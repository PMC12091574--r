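test_that("GRO round trip preserves frames, waters and coordinates", {
  set.seed(1)
  tr <- make_water_box(matrix(runif(9, 2, 8), 3, 3), box_L = 10, n_frames = 5)
  f <- tempfile(fileext = ".gro")
  write_gro(tr, f)
  back <- load_trajectory(f)
  expect_equal(n_frames(back), 5)
  expect_equal(n_waters(back), 3)
  # GRO stores nm to 3 decimals: 0.005 A quantization
  expect_lt(max(abs(back$coords - tr$coords)), 0.006)
  expect_equal(back$box[, , 1], tr$box[, , 1], tolerance = 1e-4)
})

test_that("multi-model PDB reads as a multi-frame trajectory with its box", {
  set.seed(2)
  tr <- make_water_box(matrix(runif(9, 2, 8), 3, 3), box_L = 10, n_frames = 2)
  f <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, f)
  back <- load_trajectory(f, dt = 0.5)
  expect_equal(n_frames(back), 2)
  expect_equal(back$dt, 0.5)
  expect_lt(max(abs(back$coords - tr$coords)), 1e-3)
  expect_equal(back$box[, , 1], tr$box[, , 1], tolerance = 1e-3)
})

test_that("waterless topologies and unsupported formats give clear errors", {
  tr <- make_water_box(matrix(5, 1, 3), box_L = 10)
  f <- tempfile(fileext = ".gro")
  write_gro(tr, f)
  expect_error(load_trajectory(f, water_residues = "XXX"), "no waters detected")
  expect_error(load_trajectory(f, trajectory = "traj.xtc"), "not found")
  file.create(fx <- tempfile(fileext = ".xtc"))
  expect_error(load_trajectory(f, trajectory = fx), "unsupported trajectory format")
})

test_that("water detection is invariant to atom order within a residue", {
  set.seed(3)
  o <- matrix(runif(6, 2, 8), 2, 3)
  tr <- make_water_box(o, box_L = 10)
  idx <- c(3, 1, 2, 2, 3, 1) + rep(c(0, 3), each = 3)  # scramble within residues
  coords <- tr$coords[idx, , , drop = FALSE]
  atoms <- tr$atoms[idx, ]
  tr2 <- new_trajectory(coords, diag(10, 3), atoms)
  expect_equal(n_waters(tr2), 2)
  expect_equal(tr2$coords[tr2$waters$O, , 1], tr$coords[tr$waters$O, , 1])
})

test_that("minimum image handles wraparound, identity and triclinic boxes", {
  tr <- make_water_box(rbind(c(1, 1, 1), c(9, 1, 1)), box_L = 10)
  expect_equal(minimum_image_vector(tr, 1, 4), c(-2, 0, 0))
  expect_equal(minimum_image_vector(tr, 1, 1), c(0, 0, 0))
  box <- rbind(c(10, 0, 0), c(3, 9, 0), c(-2, 1, 8))
  set.seed(4)
  for (i in 1:50) {
    d <- runif(3, -15, 15)
    expect_equal(drop(min_image(d, box)), brute_min_image(d, box),
                 tolerance = 1e-9)
  }
  expect_error(min_image(c(1, 1, 1), matrix(0, 3, 3)), "degenerate box")
})

test_that("minimum-image distances are symmetric and obey the triangle inequality", {
  box <- rbind(c(10, 0, 0), c(3, 9, 0), c(-2, 1, 8))
  set.seed(5)
  pts <- matrix(runif(30, -5, 15), 10, 3)
  mi_d <- function(a, b) sqrt(sum(min_image(b - a, box)^2))
  for (k in 1:30) {
    ijk <- sample(10, 3)
    a <- pts[ijk[1], ]; b <- pts[ijk[2], ]; cc <- pts[ijk[3], ]
    expect_equal(mi_d(a, b), mi_d(b, a), tolerance = 1e-9)
    expect_lte(mi_d(a, cc), mi_d(a, b) + mi_d(b, cc) + 1e-9)
  }
})

test_that("nearest-water selection matches a brute-force distance scan", {
  # constructed slab: 3 waters close to the site, 7 far
  o <- rbind(matrix(c(5, 5, 3, 5, 6, 3, 6, 5, 3), 3, 3, byrow = TRUE),
             matrix(runif(21, 15, 25), 7, 3))
  tr <- make_water_box(o, box_L = 40)
  sites <- tr$waters$O[1]  # use first water's O as the site
  expect_equal(sort(nearest_waters(tr, sites, 3)), 1:3)
  expect_equal(length(nearest_waters(tr, sites, 10)), 10)
  expect_error(nearest_waters(tr, sites, 11), "exceeds")
  # randomized oracle comparison
  set.seed(6)
  for (rep in 1:20) {
    o <- matrix(runif(36, 0, 12), 12, 3)
    tr <- make_water_box(o, box_L = 12)
    sites <- tr$waters$O[sample(12, 2)]
    d <- vapply(seq_len(12), function(w) {
      min(vapply(sites, function(s)
        sqrt(sum(min_image(tr$coords[tr$waters$O[w], , 1] -
                             tr$coords[s, , 1], diag(12, 3))^2)), numeric(1)))
    }, numeric(1))
    expect_equal(nearest_waters(tr, sites, 5), order(d, seq_len(12))[1:5])
  }
})

test_that("site-water RDF is flat for an ideal gas and peaked for a lattice", {
  set.seed(7)
  n <- 300; L <- 20
  tr <- make_water_box(matrix(runif(3 * n, 0, L), n, 3), box_L = L,
                       n_frames = 3)
  g <- site_water_rdf(tr, sites = tr$waters$O[1:15], r_max = 9, dr = 0.5)
  expect_lt(abs(mean(g$g[g$r > 3]) - 1), 0.1)
  # single site + single water at 3.1 A: lone nonzero bin at that distance
  tr2 <- make_water_box(rbind(c(5, 5, 5), c(8.1, 5, 5)), box_L = 20)
  g2 <- site_water_rdf(tr2, sites = tr2$waters$O[1], r_max = 6, dr = 0.5)
  nz <- which(g2$count > 0)
  expect_length(nz, 1)
  expect_lt(abs(g2$r[nz] - 3.1), 0.25)
  # lattice: first peak at the nearest-neighbor distance
  lat <- gen_tetrahedral_lattice(n_cells = 3)
  g3 <- site_water_rdf(lat, sites = lat$waters$O[1], r_max = 8, dr = 0.2)
  first <- g3$r[which(g3$g > 0)[1]]
  expect_lt(abs(first - ground_truth(lat)$nn_distance), 0.2)
  expect_error(site_water_rdf(lat, lat$waters$O[1], r_max = 8, dr = -1),
               "dr must be positive")
  expect_error(site_water_rdf(lat, lat$waters$O[1], r_max = 1e4, dr = 1),
               "half the smallest box dimension")
})
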