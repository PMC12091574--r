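## Protein-side ice-binding-surface geometry: threonine side-chain
## orientation angles (side angle theta_S against the ladder-long axis, top
## angle theta_T against the neighbor C-alpha axis), side-chain RMSD after
## backbone superposition, C-alpha ladder spacings (the 7.1 vs 6.9 A motif
## register), tyrosine C-beta stacking distances and Ser(OH)-Gly(C=O)
## distances on the conserved loops.

#' Resolve a threonine ladder's atoms
#'
#' @param traj a `wtraj` object.
#' @param resids ordered residue ids forming one ladder (>= 2 residues).
#' @param resname residue name to match (default `"THR"`).
#' @return data.frame with columns `resid`, `CA`, `CB`, `OG1` (atom
#'   indices); rows with unresolvable atoms are dropped with a warning.
#' @export
thr_ladder <- function(traj, resids, resname = "THR") {
  if (length(resids) < 2L) stop("a ladder needs at least 2 residues")
  rows <- lapply(resids, function(r) {
    find <- function(nm) {
      i <- select_atoms(traj, resname = resname, name = nm, resid = r)
      if (length(i) == 1L) i else NA_integer_
    }
    data.frame(resid = r, CA = find("CA"), CB = find("CB"), OG1 = find("OG1"))
  })
  out <- do.call(rbind, rows)
  bad <- !stats::complete.cases(out)
  if (any(bad)) {
    warning("skipping residues with unresolvable atoms: ",
            paste(out$resid[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) < 2L) stop("fewer than 2 resolvable ladder residues")
  out
}

## per-frame angle between `axis` (n x 3 or fixed) and CB -> OG1 of a residue
.cb_og1_angles <- function(traj, cb, og1, axis_fun) {
  nf <- n_frames(traj)
  vapply(seq_len(nf), function(f) {
    v <- traj$coords[og1, , f] - traj$coords[cb, , f]
    .vec_angle(axis_fun(f), v)
  }, numeric(1))
}

#' Side angle theta_S of threonine hydroxyls
#'
#' Angle between the ladder-long axis (C-alpha of the x-residues of the TxT
#' patch on the first and last strand) and each residue's C-beta to
#' hydroxyl-oxygen vector, per frame.
#'
#' @param traj a `wtraj` object.
#' @param ladder a [thr_ladder()] data.frame.
#' @param axis_atoms length-2 atom indices (C-alpha pair defining the axis).
#' @return data.frame: `resid`, `frame`, `angle` (degrees).
#' @export
theta_S <- function(traj, ladder, axis_atoms) {
  stopifnot(length(axis_atoms) == 2L)
  axis_fun <- function(f) traj$coords[axis_atoms[2], , f] -
    traj$coords[axis_atoms[1], , f]
  out <- lapply(seq_len(nrow(ladder)), function(i) {
    data.frame(resid = ladder$resid[i], frame = seq_len(n_frames(traj)),
               angle = .cb_og1_angles(traj, ladder$CB[i], ladder$OG1[i], axis_fun))
  })
  do.call(rbind, out)
}

#' Top angle theta_T of threonine hydroxyls
#'
#' Angle between the axis joining a residue's C-alpha to its same-strand
#' neighbor threonine's C-alpha and the residue's C-beta to hydroxyl-oxygen
#' vector. The last ladder residue has no forward neighbor and is skipped.
#'
#' @param traj a `wtraj` object.
#' @param ladder a [thr_ladder()] data.frame (consecutive rows are
#'   same-strand neighbors).
#' @return data.frame: `resid`, `frame`, `angle` (degrees).
#' @export
theta_T <- function(traj, ladder) {
  n <- nrow(ladder)
  out <- lapply(seq_len(n - 1L), function(i) {
    axis_fun <- function(f) traj$coords[ladder$CA[i + 1L], , f] -
      traj$coords[ladder$CA[i], , f]
    data.frame(resid = ladder$resid[i], frame = seq_len(n_frames(traj)),
               angle = .cb_og1_angles(traj, ladder$CB[i], ladder$OG1[i], axis_fun))
  })
  do.call(rbind, out)
}

#' Normalized angle distribution
#'
#' @param angles vector of angles in degrees.
#' @param bin bin width in degrees (default 2, matching the presentation of
#'   side/top angle panels).
#' @return data.frame: `mid`, `density` (integrates to 1 over degrees).
#' @export
angle_distribution <- function(angles, bin = 2) {
  breaks <- seq(0, 180, by = bin)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, density = h$counts / sum(h$counts) / diff(breaks))
}

#' Side-chain RMSD after backbone superposition
#'
#' Each frame is least-squares superposed onto the reference frame using
#' backbone atoms (CA, C, N of all non-water residues), then the RMSD of
#' each listed residue's side-chain heavy atoms is computed.
#'
#' @param traj a `wtraj` object.
#' @param resids residue ids to report.
#' @param reference_frame reference frame (default 1).
#' @return data.frame: `resid`, `frame`, `rmsd` (Angstrom).
#' @export
sidechain_rmsd <- function(traj, resids, reference_frame = 1L) {
  at <- traj$atoms
  is_water <- seq_len(nrow(at)) %in% with(traj$waters, c(O, H1, H2))
  bb <- which(at$name %in% c("CA", "C", "N") & !is_water)
  if (length(bb) < 3L) stop("fewer than 3 backbone atoms for superposition")
  bb_xyz_idx <- as.numeric(t(outer(bb, c(0, 1, 2) , function(i, k) 3 * (i - 1) + k + 1)))
  nf <- n_frames(traj)
  xyz <- t(apply(traj$coords, 3, function(m) as.numeric(t(m))))
  if (nf == 1L) xyz <- matrix(xyz, nrow = 1)
  fitted <- bio3d::fit.xyz(fixed = xyz[reference_frame, ], mobile = xyz,
                           fixed.inds = bb_xyz_idx, mobile.inds = bb_xyz_idx)
  backbone_names <- c("N", "CA", "C", "O", "H", "HA", "OXT")
  out <- lapply(resids, function(r) {
    sc <- which(at$resid == r & !is_water &
                  !(at$name %in% backbone_names) &
                  .element_of(at$name) != "H")
    if (!length(sc)) stop("no side-chain heavy atoms for residue ", r)
    cols <- as.numeric(t(outer(sc, 0:2, function(i, k) 3 * (i - 1) + k + 1)))
    ref <- fitted[reference_frame, cols]
    rmsd <- vapply(seq_len(nf), function(f)
      sqrt(mean(matrix((fitted[f, cols] - ref)^2, ncol = 3) %*% c(1, 1, 1))),
      numeric(1))
    data.frame(resid = r, frame = seq_len(nf), rmsd = rmsd)
  })
  do.call(rbind, out)
}

#' Mean C-alpha spacing of a threonine ladder
#'
#' Two readings of the motif spacing are provided: `intra_strand_TxT`
#' measures consecutive threonines along one strand (separated by one x
#' residue), `inter_strand_ladder` measures position-matched threonines on
#' two strands (adjacent solenoid layers). Both are reported because the
#' published 7.1 / 6.9 A register can be read either way.
#'
#' @param traj a `wtraj` object.
#' @param ladder a [thr_ladder()] for the (first) strand.
#' @param mode `"intra_strand_TxT"` or `"inter_strand_ladder"`.
#' @param ladder2 second-strand [thr_ladder()] (required for the
#'   inter-strand mode).
#' @return list with `mean` (Angstrom), `per_pair` data.frame
#'   (`pair`, `mean`), `mode`.
#' @export
ladder_spacing <- function(traj, ladder,
                           mode = c("intra_strand_TxT", "inter_strand_ladder"),
                           ladder2 = NULL) {
  mode <- match.arg(mode)
  nf <- n_frames(traj)
  if (mode == "intra_strand_TxT") {
    if (nrow(ladder) < 2L) stop("no qualifying pairs")
    pairs <- cbind(ladder$CA[-nrow(ladder)], ladder$CA[-1])
  } else {
    if (is.null(ladder2)) stop("inter_strand_ladder mode requires ladder2")
    n <- min(nrow(ladder), nrow(ladder2))
    if (n < 1L) stop("no qualifying pairs")
    pairs <- cbind(ladder$CA[seq_len(n)], ladder2$CA[seq_len(n)])
  }
  per_pair <- vapply(seq_len(nrow(pairs)), function(p) {
    mean(vapply(seq_len(nf), function(f)
      sqrt(sum(min_image(traj$coords[pairs[p, 2], , f] -
                           traj$coords[pairs[p, 1], , f],
                         traj$box[, , f])^2)), numeric(1)))
  }, numeric(1))
  list(mean = mean(per_pair),
       per_pair = data.frame(pair = seq_along(per_pair), mean = per_pair),
       mode = mode)
}

#' Adjacent-pair distance series between listed atoms
#'
#' Shared backend for tyrosine C-beta stacking and Ser-Gly hydrogen-bond
#' distance distributions.
#'
#' @param traj a `wtraj` object.
#' @param atoms_a,atoms_b equal-length atom index vectors; pair i is
#'   (`atoms_a[i]`, `atoms_b[i]`).
#' @return data.frame: `pair`, `frame`, `distance` (Angstrom).
#' @keywords internal
.pair_distance_series <- function(traj, atoms_a, atoms_b) {
  stopifnot(length(atoms_a) == length(atoms_b))
  if (any(atoms_a == atoms_b)) stop("identical atoms in a pair")
  nf <- n_frames(traj)
  out <- lapply(seq_along(atoms_a), function(p) {
    d <- vapply(seq_len(nf), function(f)
      sqrt(sum(min_image(traj$coords[atoms_b[p], , f] -
                           traj$coords[atoms_a[p], , f],
                         traj$box[, , f])^2)), numeric(1))
    data.frame(pair = p, frame = seq_len(nf), distance = d)
  })
  do.call(rbind, out)
}

#' Tyrosine stacking distances
#'
#' Per-frame C-beta to C-beta distances between adjacent tyrosines along the
#' solenoid; stable stacking shows as sharp, coincident distributions.
#'
#' @param traj a `wtraj` object.
#' @param tyr_cb ordered C-beta atom indices of the tyrosines (>= 2).
#' @return list with `series` (data.frame `pair`, `frame`, `distance`) and
#'   `summary` (per-pair mean, sd, IQR).
#' @export
stacking_distances <- function(traj, tyr_cb) {
  if (length(tyr_cb) < 2L) stop("need at least 2 tyrosines")
  series <- .pair_distance_series(traj, tyr_cb[-length(tyr_cb)], tyr_cb[-1])
  list(series = series, summary = .dist_summary(series))
}

#' Serine-glycine hydrogen-bond distances on conserved loops
#'
#' Per-loop distances between the serine hydroxyl oxygen and the glycine
#' carbonyl oxygen; a persistent H-bond shows as a sharp distribution
#' (small IQR), a broken one as a broad distribution.
#'
#' @param traj a `wtraj` object.
#' @param ser_og,gly_o equal-length atom index vectors (one entry per loop).
#' @return list with `series` and `summary` (per-loop mean, sd, IQR).
#' @export
ser_gly_distances <- function(traj, ser_og, gly_o) {
  series <- .pair_distance_series(traj, ser_og, gly_o)
  list(series = series, summary = .dist_summary(series))
}

.dist_summary <- function(series) {
  sp <- split(series$distance, series$pair)
  data.frame(pair = as.integer(names(sp)),
             mean = vapply(sp, mean, numeric(1)),
             sd = vapply(sp, sd, numeric(1)),
             iqr = vapply(sp, function(x) diff(quantile(x, c(0.25, 0.75))),
                          numeric(1)))
}
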