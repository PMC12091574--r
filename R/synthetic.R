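## Synthetic trajectory generators with analytic ground truth.
##
## Each generator seeds its own RNG, emits a regular `wtraj` (so the whole
## analysis path, including file I/O via write_gro()/write_multimodel_pdb(),
## can be exercised) and records its analytic ground truth in a
## `ground_truth` attribute.  The generators are geometric stand-ins, not
## physics: no force field, no thermostat, no proton-disorder sampling.

#' Ground-truth record of a synthetic trajectory
#'
#' @param x a generator output.
#' @return the generator's analytic ground-truth list.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

## rigid 3-site water geometry: O-H 0.9572 A, H-O-H 104.52 deg, dipole +z
.water_template <- function() {
  half <- .rad(104.52 / 2)
  rbind(H1 = 0.9572 * c(sin(half), 0, cos(half)),
        H2 = 0.9572 * c(-sin(half), 0, cos(half)))
}

.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.water_atom_table <- function(n, resid_start = 1L, resname = "SOL") {
  data.frame(name = rep(c("OW", "HW1", "HW2"), n),
             resname = resname,
             resid = rep(resid_start + seq_len(n) - 1L, each = 3L))
}

## ---- tetrahedral lattice ---------------------------------------------------

## Eulerian orientation of a connected even-degree multigraph: direct each
## edge along the traversal of a closed trail decomposition, giving equal
## in/out degree at every vertex (out-degree 2 on the 4-regular O-O graph,
## i.e. the ice rule: every water donates exactly two hydrogens).
.eulerian_orientation <- function(edges, nv) {
  m <- nrow(edges)
  adj <- vector("list", nv)
  for (e in seq_len(m)) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], e)
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], e)
  }
  ptr <- rep(1L, nv)
  used <- logical(m)
  from <- integer(m); to <- integer(m)
  for (start in seq_len(nv)) {
    if (ptr[start] > length(adj[[start]])) next
    vstack <- start
    while (length(vstack)) {
      v <- vstack[length(vstack)]
      advanced <- FALSE
      while (ptr[v] <= length(adj[[v]])) {
        e <- adj[[v]][ptr[v]]
        ptr[v] <- ptr[v] + 1L
        if (!used[e]) {
          used[e] <- TRUE
          w <- if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
          from[e] <- v; to[e] <- w
          vstack <- c(vstack, w)
          advanced <- TRUE
          break
        }
      }
      if (!advanced) vstack <- vstack[-length(vstack)]
    }
  }
  cbind(from = from, to = to)
}

#' Generate an ice-like tetrahedral water lattice
#'
#' Diamond-cubic oxygen lattice in a cubic periodic box, with every water
#' donating two hydrogens along neighbor directions (ice rule, satisfied by
#' an Eulerian orientation of the O-O bond graph). At zero jitter every
#' O-O-O angle is the tetrahedral angle (109.47 deg), every water donates
#' and accepts two H-bonds, and t_h = 1 for every water. Gaussian rigid-body
#' positional jitter of width `jitter` is applied per frame and water.
#' Note the donated hydrogens subtend the tetrahedral angle (109.47 deg)
#' rather than the free-water 104.52 deg; the geometric criteria downstream
#' only see O and H positions, for which this is immaterial.
#'
#' The ground truth records the lattice constant, nearest-neighbor distance,
#' and an independent brute-force per-water H-bond count (27-image direct
#' search, no shared code with the detector).
#'
#' @param a cubic lattice constant in Angstrom (default 6.35, giving the
#'   ice-like O-O distance 2.75 A).
#' @param n_cells unit cells per box edge (>= 2).
#' @param jitter Gaussian rigid-body displacement sd per frame, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a `wtraj` with `ground_truth(x)` populated.
#' @export
gen_tetrahedral_lattice <- function(a = 6.35, n_cells = 2L, jitter = 0,
                                    n_frames = 1L, seed = 1L) {
  if (a <= 0) stop("lattice constant must be positive")
  if (jitter < 0) stop("jitter must be non-negative")
  if (n_cells < 2L) stop("box must span at least 2 cells")
  set.seed(seed)
  basis <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  basis <- rbind(basis, sweep(basis, 2, c(.25, .25, .25), "+"))
  cells <- as.matrix(expand.grid(0:(n_cells - 1), 0:(n_cells - 1),
                                 0:(n_cells - 1)))
  o_frac <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    sweep(basis, 2, cells[i, ], "+"))) / n_cells
  L <- a * n_cells
  o <- o_frac * L
  nw <- nrow(o)
  nn <- a * sqrt(3) / 4
  ## neighbor graph under PBC
  edges <- NULL
  for (i in seq_len(nw - 1)) {
    d <- sweep(o[(i + 1):nw, , drop = FALSE], 2, o[i, ])
    d <- d - round(d / L) * L
    r <- sqrt(rowSums(d^2))
    hit <- which(abs(r - nn) < 1e-6)
    if (length(hit)) edges <- rbind(edges, cbind(i, i + hit))
  }
  stopifnot(nrow(edges) == 2L * nw)  # 4-regular
  orient <- .eulerian_orientation(edges, nw)
  out_deg <- tabulate(orient[, "from"], nbins = nw)
  stopifnot(all(out_deg == 2L))
  ## place H along the two donated bond directions
  coords1 <- matrix(NA_real_, 3L * nw, 3L)
  for (i in seq_len(nw)) {
    eo <- which(orient[, "from"] == i)
    hs <- t(vapply(eo, function(e) {
      d <- o[orient[e, "to"], ] - o[i, ]
      d <- d - round(d / L) * L
      o[i, ] + 0.9572 * d / sqrt(sum(d^2))
    }, numeric(3)))
    coords1[3 * i - 2, ] <- o[i, ]
    coords1[3 * i - 1, ] <- hs[1, ]
    coords1[3 * i, ] <- hs[2, ]
  }
  coords <- array(NA_real_, c(3L * nw, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    shift <- if (jitter > 0)
      matrix(rnorm(3L * nw, sd = jitter), nw, 3L) else matrix(0, nw, 3L)
    fr <- coords1
    for (i in seq_len(nw)) {
      rows <- (3 * i - 2):(3 * i)
      fr[rows, ] <- sweep(fr[rows, , drop = FALSE], 2, shift[i, ], "+")
    }
    coords[, , f] <- fr
  }
  atoms <- .water_atom_table(nw)
  traj <- new_trajectory(coords, diag(L, 3), atoms)
  hb <- .brute_force_hbond_counts(coords, L, nw, r_cut = 3.5, angle_cut = 30)
  attr(traj, "ground_truth") <- list(
    generator = "tetrahedral_lattice", a = a, nn_distance = nn,
    ooo_angle = .deg(acos(-1 / 3)), jitter = jitter, seed = seed,
    hbond_counts = hb)
  traj
}

## independent brute-force H-bond counter (donated + accepted per water):
## direct 27-image search on a cubic box, deviation-angle criterion.
.brute_force_hbond_counts <- function(coords, L, nw, r_cut, angle_cut) {
  nf <- dim(coords)[3]
  shifts <- as.matrix(expand.grid(c(-L, 0, L), c(-L, 0, L), c(-L, 0, L)))
  counts <- matrix(0L, nf, nw)
  for (f in seq_len(nf)) {
    xyz <- coords[, , f]
    for (dnr in seq_len(nw)) {
      od <- xyz[3 * dnr - 2, ]
      for (acc in seq_len(nw)) {
        if (acc == dnr) next
        oa_img <- sweep(shifts, 2, xyz[3 * acc - 2, ], "+")
        r_all <- sqrt(rowSums(sweep(oa_img, 2, od)^2))
        best <- which.min(r_all)
        r <- r_all[best]
        if (r > r_cut) next
        doa <- oa_img[best, ] - od
        for (h in c(3 * dnr - 1, 3 * dnr)) {
          oh <- xyz[h, ] - od
          ang <- .deg(acos(min(1, max(-1, sum(oh * doa) /
                                        sqrt(sum(oh^2) * sum(doa^2))))))
          if (ang <= angle_cut) {
            counts[f, dnr] <- counts[f, dnr] + 1L
            counts[f, acc] <- counts[f, acc] + 1L
          }
        }
      }
    }
  }
  counts
}

## ---- orientation laws ------------------------------------------------------

#' Generate orientation-angle samples with analytic rotational entropy
#'
#' Draws `(theta, chi)` samples from a prescribed orientational law and
#' records the analytic `T*S_Rot` the estimator should recover. Under the
#' uniform law theta follows the sin(theta) measure and chi is uniform, so
#' the entropy is exactly zero; `half_domain` restricts theta to [0, 90]
#' (entropy `-k_B T ln 2`); `single_bin` confines samples to one grid bin of
#' measure `dOmega` (entropy `-k_B T ln(c / dOmega)`); `concentrated` tilts
#' theta by `exp(kappa cos theta)` with the entropy evaluated by numeric
#' quadrature; `mixture` draws one concentrated stream per element of
#' `kappa`.
#'
#' @param law one of `"uniform"`, `"half_domain"`, `"single_bin"`,
#'   `"concentrated"`, `"mixture"`.
#' @param n samples (per label for `mixture`).
#' @param seed RNG seed.
#' @param T temperature in kelvin (default 273).
#' @param kappa concentration parameter (scalar, or vector for `mixture`).
#' @param grid,bin for `single_bin`: the angular grid and the
#'   `(theta_bin, chi_bin)` index of the occupied bin.
#' @return list with `theta`, `chi` (degrees), `ts_rot_true` (kcal/mol) and
#'   the parameters; for `mixture`, a list of such lists plus the truth
#'   vector.
#' @export
gen_oriented_waters <- function(law = c("uniform", "half_domain", "single_bin",
                                        "concentrated", "mixture"),
                                n, seed = 1L, T = 273, kappa = 4,
                                grid = c(30, 30), bin = c(1L, 1L)) {
  law <- match.arg(law)
  set.seed(seed)
  draw_conc <- function(n, kap) {
    x <- if (abs(kap) < 1e-12) runif(n, -1, 1) else
      log(exp(-kap) + runif(n) * (exp(kap) - exp(-kap))) / kap
    list(theta = .deg(acos(x)), chi = runif(n, 0, 180))
  }
  conc_entropy <- function(kap, T) {
    if (abs(kap) < 1e-12) return(0)
    zx <- stats::integrate(function(x) exp(kap * x), -1, 1)$value
    ex <- stats::integrate(function(x) x * exp(kap * x), -1, 1)$value / zx
    ## S = -k_B (kappa E[cos theta] - ln Z + ln c), Z = pi * zx, c = 2*pi
    -T * .kB * (kap * ex - log(pi * zx) + log(2 * pi))
  }
  if (law == "uniform") {
    s <- draw_conc(n, 0)
    return(c(s, list(law = law, ts_rot_true = 0, T = T, seed = seed)))
  }
  if (law == "half_domain") {
    x <- runif(n, 0, 1)
    return(list(theta = .deg(acos(x)), chi = runif(n, 0, 180), law = law,
                ts_rot_true = -.kB * T * log(2), T = T, seed = seed))
  }
  if (law == "single_bin") {
    te <- seq(0, 180, length.out = grid[1] + 1)
    ce <- seq(0, 180, length.out = grid[2] + 1)
    clo <- cos(.rad(te[bin[1] + 1])); chi_ <- cos(.rad(te[bin[1]]))
    x <- runif(n, clo, chi_)
    chi_s <- runif(n, ce[bin[2]], ce[bin[2] + 1])
    d_omega <- (chi_ - clo) * .rad(ce[bin[2] + 1] - ce[bin[2]])
    return(list(theta = .deg(acos(x)), chi = chi_s, law = law,
                ts_rot_true = -.kB * T * log(2 * pi / d_omega),
                d_omega = d_omega, grid = grid, bin = bin, T = T, seed = seed))
  }
  if (law == "concentrated") {
    s <- draw_conc(n, kappa)
    return(c(s, list(law = law, kappa = kappa,
                     ts_rot_true = conc_entropy(kappa, T), T = T, seed = seed)))
  }
  ## mixture: one stream per kappa
  streams <- lapply(kappa, function(k) c(draw_conc(n, k), list(kappa = k)))
  list(law = "mixture", streams = streams,
       ts_rot_true = vapply(kappa, conc_entropy, numeric(1), T = T),
       kappa = kappa, T = T, seed = seed)
}

## ---- two-state exchange ----------------------------------------------------

#' Generate a two-state shell-exchange trajectory
#'
#' Each water sits above its own hydroxyl-bearing pseudo-residue and hops as
#' a Markov chain between a bound slot (hydroxyl donates to the water O at
#' 2.8 A, deviation angle 0: satisfies the 3.5 A / 35 deg reactant
#' criterion) and a far slot beyond the 5.3 A product cutoff. With no
#' return, the analytic survival is `C(t) = exp(-k_exit t)` per water and
#' the mean residence time is `1/k_exit`; a vector `k_exit` yields a
#' mixture of populations.
#'
#' @param k_exit exit rate(s) in 1/ps (recycled over waters).
#' @param k_return return rate in 1/ps (default 0).
#' @param n_waters number of waters.
#' @param dt frame spacing in ps (default 0.1). A warning is issued when
#'   `dt * max(k_exit) > 0.1` (time step too coarse).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param spacing lateral spacing between pseudo-residues, Angstrom.
#' @return a `wtraj`; `ground_truth(x)` carries the `bound` state matrix
#'   (`n_frames x n_waters`), the rates, per-water `tau_true`, and the site
#'   index lists (`hydroxyls`, `ibs_sites`).
#' @export
gen_exchange_trajectory <- function(k_exit, k_return = 0, n_waters = 50L,
                                    dt = 0.1, n_frames = 500L, seed = 1L,
                                    spacing = 25) {
  if (any(k_exit < 0) || k_return < 0) stop("rates must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (dt * max(k_exit) > 0.1)
    warning("dt * k_exit > 0.1: time step too coarse for the fastest rate")
  set.seed(seed)
  kx <- rep_len(k_exit, n_waters)
  p_exit <- 1 - exp(-kx * dt)
  p_ret <- 1 - exp(-k_return * dt)
  bound <- matrix(FALSE, n_frames, n_waters)
  bound[1, ] <- TRUE
  for (f in 2:n_frames) {
    u <- runif(n_waters)
    bound[f, ] <- ifelse(bound[f - 1, ], u > p_exit, u < p_ret)
  }
  ncol_g <- ceiling(sqrt(n_waters))
  gx <- ((seq_len(n_waters) - 1) %% ncol_g) * spacing + spacing / 2
  gy <- ((seq_len(n_waters) - 1) %/% ncol_g) * spacing + spacing / 2
  Lx <- ncol_g * spacing
  Ly <- ceiling(n_waters / ncol_g) * spacing
  ## pseudo-residue: CA, CB, OG1, HG1 on a vertical stem; hydroxyl donates up
  res_at <- function(x, y) rbind(c(x, y, 0.5), c(x, y, 1.7),
                                 c(x, y, 2.9), c(x, y, 3.87))
  wt <- .water_template()
  prot <- do.call(rbind, lapply(seq_len(n_waters), function(i) res_at(gx[i], gy[i])))
  n_prot <- nrow(prot)
  coords <- array(NA_real_, c(n_prot + 3L * n_waters, 3L, n_frames))
  z_bound <- 2.9 + 2.8
  z_far <- 2.9 + 13
  o_rows <- n_prot + seq(1L, 3L * n_waters, by = 3L)
  for (f in seq_len(n_frames)) {
    z <- ifelse(bound[f, ], z_bound, z_far)
    coords[seq_len(n_prot), , f] <- prot
    coords[o_rows, , f] <- cbind(gx, gy, z)
    coords[o_rows + 1L, , f] <- cbind(gx + wt[1, 1], gy + wt[1, 2], z + wt[1, 3])
    coords[o_rows + 2L, , f] <- cbind(gx + wt[2, 1], gy + wt[2, 2], z + wt[2, 3])
  }
  atoms <- rbind(
    data.frame(name = rep(c("CA", "CB", "OG1", "HG1"), n_waters),
               resname = "THR",
               resid = rep(seq_len(n_waters), each = 4L)),
    .water_atom_table(n_waters, resid_start = n_waters + 1L))
  traj <- new_trajectory(coords, diag(c(Lx, Ly, 40)), atoms, dt = dt)
  og1 <- which(atoms$name == "OG1")
  hg1 <- which(atoms$name == "HG1")
  tau_true <- ifelse(kx > 0, 1 / kx, Inf)
  attr(traj, "ground_truth") <- list(
    generator = "exchange", k_exit = kx, k_return = k_return,
    bound = bound, tau_true = tau_true,
    tau_mean_true = mean(tau_true),
    hydroxyls = list(O = og1, H = hg1), ibs_sites = og1,
    dt = dt, seed = seed)
  traj
}

## ---- Brownian box ----------------------------------------------------------

#' Generate independent Brownian waters in a periodic box
#'
#' Isotropic Gaussian steps of per-axis variance `2 D dt`, wrapped into a
#' cubic box; the unwrapped truth is retained in the ground truth so the
#' Einstein relation `MSD(t) = 6 D t` is exactly recoverable.
#'
#' @param D diffusion coefficient in Angstrom^2/ps (>= 0).
#' @param n_waters number of waters.
#' @param dt frame spacing in ps.
#' @param n_frames number of frames.
#' @param box_L cubic box edge, Angstrom.
#' @param seed RNG seed.
#' @return a `wtraj`; `ground_truth(x)$unwrapped` is an
#'   `n_frames x 3 x n_waters` array of unwrapped O positions.
#' @export
gen_brownian_box <- function(D, n_waters = 100L, dt = 0.1, n_frames = 100L,
                             box_L = 30, seed = 1L) {
  if (D < 0) stop("D must be non-negative")
  set.seed(seed)
  start <- matrix(runif(3L * n_waters, 0, box_L), n_waters, 3L)
  un <- array(NA_real_, c(n_frames, 3L, n_waters))
  for (w in seq_len(n_waters)) {
    steps <- matrix(rnorm(3L * (n_frames - 1L), sd = sqrt(2 * D * dt)),
                    n_frames - 1L, 3L)
    cum <- apply(steps, 2, cumsum)
    if (n_frames == 2L) cum <- matrix(cum, 1L, 3L)
    un[, , w] <- rbind(start[w, ], sweep(cum, 2, start[w, ], "+"))
  }
  wt <- .water_template()
  coords <- array(NA_real_, c(3L * n_waters, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    ow <- t(un[f, , ]) %% box_L
    coords[seq(1, 3 * n_waters, by = 3), , f] <- ow
    coords[seq(2, 3 * n_waters, by = 3), , f] <- sweep(ow, 2, wt[1, ], "+")[, ]
    coords[seq(3, 3 * n_waters, by = 3), , f] <- sweep(ow, 2, wt[2, ], "+")[, ]
  }
  atoms <- .water_atom_table(n_waters)
  traj <- new_trajectory(coords, diag(box_L, 3), atoms, dt = dt)
  attr(un, "dt") <- dt
  attr(traj, "ground_truth") <- list(generator = "brownian", D = D,
                                     unwrapped = un, dt = dt, seed = seed)
  traj
}

## ---- toy ice-binding surface ----------------------------------------------

#' Generate a toy planar ice-binding surface with a water slab
#'
#' A planar grid of hydroxyl-bearing pseudo-threonines (CA, CB, OG1, HG1 on
#' vertical stems, default spacing 7.4 A matching the TxT register) under a
#' slab of waters. The first `n_pinned` waters are pinned at perfect
#' bonding geometry above the first sites with frozen orientation; the
#' remaining waters are re-oriented at random and positionally jittered
#' every frame, far from the surface.
#'
#' @param n_rows,n_cols grid dimensions of the pseudo-residue plane.
#' @param spacing grid spacing, Angstrom (default 7.4).
#' @param n_free free (mobile, randomly re-oriented) waters.
#' @param n_pinned waters pinned at bonding geometry (default 2).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param free_jitter positional jitter sd of free waters per frame.
#' @return a `wtraj`; `ground_truth(x)` carries `sites` (lists `ca`, `cb`,
#'   `og1`, `hg1`), `pinned_labels`, and the construction parameters.
#' @export
gen_toy_ibs <- function(n_rows = 2L, n_cols = 3L, spacing = 7.4,
                        n_free = 8L, n_pinned = 2L, n_frames = 5L,
                        seed = 1L, free_jitter = 0.3) {
  if (spacing <= 0) stop("spacing must be positive")
  n_sites <- n_rows * n_cols
  if (n_pinned > n_sites) stop("more pinned waters than sites")
  set.seed(seed)
  gx <- rep(seq_len(n_cols) - 1, times = n_rows) * spacing + spacing
  gy <- rep(seq_len(n_rows) - 1, each = n_cols) * spacing + spacing
  Lx <- (n_cols + 1) * spacing; Ly <- (n_rows + 1) * spacing; Lz <- 30
  res_at <- function(x, y) rbind(c(x, y, 0.5), c(x, y, 1.7),
                                 c(x, y, 2.9), c(x, y, 3.87))
  prot <- do.call(rbind, lapply(seq_len(n_sites), function(i) res_at(gx[i], gy[i])))
  wt <- .water_template()
  nw <- n_pinned + n_free
  coords <- array(NA_real_, c(nrow(prot) + 3L * nw, 3L, n_frames))
  free_xy <- cbind(runif(n_free, 0, Lx), runif(n_free, 0, Ly),
                   runif(n_free, 14, 22))
  for (f in seq_len(n_frames)) {
    wat <- matrix(NA_real_, 3L * nw, 3L)
    for (i in seq_len(n_pinned)) {
      o <- c(gx[i], gy[i], 2.9 + 2.8)
      ## fixed 30-degree tilt about x so the dipole is not collinear with the
      ## water-to-hydroxyl vector (which would leave chi undefined); the bond
      ## geometry is set by the hydroxyl donor and is unaffected
      ca <- cos(.rad(30)); sa <- sin(.rad(30))
      Rx <- matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE)
      wat[(3 * i - 2):(3 * i), ] <- rbind(o, sweep(wt %*% t(Rx), 2, o, "+"))
    }
    for (j in seq_len(n_free)) {
      i <- n_pinned + j
      o <- free_xy[j, ] + rnorm(3, sd = free_jitter)
      R <- .random_rotation()
      wat[(3 * i - 2):(3 * i), ] <- rbind(o, sweep(wt %*% t(R), 2, o, "+"))
    }
    coords[, , f] <- rbind(prot, wat)
  }
  atoms <- rbind(
    data.frame(name = rep(c("CA", "CB", "OG1", "HG1"), n_sites),
               resname = "THR", resid = rep(seq_len(n_sites), each = 4L)),
    .water_atom_table(nw, resid_start = n_sites + 1L))
  traj <- new_trajectory(coords, diag(c(Lx, Ly, Lz)), atoms)
  nm <- atoms$name
  attr(traj, "ground_truth") <- list(
    generator = "toy_ibs",
    sites = list(ca = which(nm == "CA"), cb = which(nm == "CB"),
                 og1 = which(nm == "OG1"), hg1 = which(nm == "HG1")),
    pinned_labels = seq_len(n_pinned), spacing = spacing,
    n_free = n_free, seed = seed)
  traj
}
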