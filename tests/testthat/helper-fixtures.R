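# Fixture builders shared across test files. All fixtures are built in code;
# nothing is read from disk except files the tests themselves write.

kB <- 0.0019872041

# a box of n rigid waters at given O positions (matrix n x 3), H's at fixed
# offsets unless `orientations` (list of 3x3 rotation matrices) is given
make_water_box <- function(o_pos, box_L, n_frames = 1, orientations = NULL,
                           dt = 0.1) {
  n <- nrow(o_pos)
  half <- 104.52 / 2 * pi / 180
  wt <- rbind(0.9572 * c(sin(half), 0, cos(half)),
              0.9572 * c(-sin(half), 0, cos(half)))
  coords <- array(NA_real_, c(3 * n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    for (i in seq_len(n)) {
      R <- if (is.null(orientations)) diag(3) else orientations[[i]]
      coords[3 * i - 2, , f] <- o_pos[i, ]
      coords[(3 * i - 1):(3 * i), , f] <- sweep(wt %*% t(R), 2, o_pos[i, ], "+")
    }
  }
  atoms <- data.frame(name = rep(c("OW", "HW1", "HW2"), n), resname = "SOL",
                      resid = rep(seq_len(n), each = 3))
  new_trajectory(coords, diag(box_L, 3), atoms, dt = dt)
}

# brute-force minimum image over a 5x5x5 image search (independent of the
# package's rounding+refinement implementation)
brute_min_image <- function(d, box) {
  shifts <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  imgs <- shifts %*% box
  cand <- sweep(imgs, 2, d, "+")
  cand[which.min(rowSums(cand^2)), ]
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# exhaustive minimum-cost assignment for small n
brute_assignment_cost <- function(frame_o, ref_o, box) {
  n <- nrow(ref_o)
  perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  costs <- apply(perms, 1, function(p)
    sum(vapply(seq_len(n), function(i)
      sum(min_image(frame_o[p[i], ] - ref_o[i, ], box)^2), numeric(1))))
  min(costs)
}

# minimal protein + one far-away water (the trajectory model requires at
# least one water); THR residues with N/CA/C backbone and CB/OG1/HG1
make_toy_protein <- function(n_thr = 3, spacing = 6.9, n_frames = 1,
                             jitter = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  coords1 <- NULL
  for (i in seq_len(n_thr)) {
    x <- (i - 1) * spacing
    base <- rbind(c(x, 0, 0), c(x, 1.5, 0), c(x, 3.0, 0),    # N, CA, C
                  c(x, 1.5, 1.5), c(x, 1.5, 3.0))            # CB, OG1
    coords1 <- rbind(coords1, base)
    rows[[i]] <- data.frame(name = c("N", "CA", "C", "CB", "OG1"),
                            resname = "THR", resid = i)
  }
  water <- rbind(c(30, 30, 30), c(30.96, 30, 30), c(29.76, 30.93, 30))
  coords1 <- rbind(coords1, water)
  atoms <- rbind(do.call(rbind, rows),
                 data.frame(name = c("OW", "HW1", "HW2"), resname = "SOL",
                            resid = 999))
  coords <- array(NA_real_, c(nrow(coords1), 3, n_frames))
  n_prot <- nrow(coords1) - 3L  # keep the dummy water rigid
  for (f in seq_len(n_frames)) {
    coords[, , f] <- coords1
    if (jitter > 0)
      coords[seq_len(n_prot), , f] <- coords1[seq_len(n_prot), ] +
        matrix(rnorm(3 * n_prot, sd = jitter), n_prot, 3)
  }
  new_trajectory(coords, diag(80, 3), atoms)
}
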