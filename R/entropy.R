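## Per-water rotational and translational entropy.
##
## The orientation of a water relative to a solute reference point is reduced
## to two angles: theta, between the water-O -> solute vector and the dipole
## (O -> midpoint(H1,H2)); and chi, between the normal of the (solute vector,
## dipole) plane and the H1 -> H2 vector.  The rotational entropy is the
## relative entropy of the binned density p(theta, chi) against the uniform
## orientational distribution:
##
##   S_Rot = -k_B sum_bins p c ln(p c) sin(theta) dtheta dchi
##
## with c the total angular measure of the domain (2*pi for theta, chi in
## [0, 180] degrees in radian measure), so an exactly uniform density gives
## S_Rot = 0 and any structuring gives S_Rot < 0 in expectation.  Reported
## throughout as T*S in kcal/mol.

#' Water orientation angles relative to a solute point
#'
#' @param o,h1,h2 water O / H1 / H2 positions: 3-vectors or `n x 3` matrices
#'   (one row per frame).
#' @param solute solute reference point: 3-vector or `n x 3` matrix.
#' @param box optional `3 x 3` lattice matrix; when given, the O->solute
#'   displacement is taken under the minimum-image convention.
#' @return data.frame with columns `theta`, `chi` (degrees, in [0, 180]) and
#'   `ok` (FALSE where the plane normal is degenerate, i.e. dipole parallel
#'   to the solute vector; such samples must be excluded and counted).
#' @export
orientation_angles <- function(o, h1, h2, solute, box = NULL) {
  o <- rbind(o); h1 <- rbind(h1); h2 <- rbind(h2); solute <- rbind(solute)
  n <- max(nrow(o), nrow(solute))
  expand <- function(m) if (nrow(m) == n) m else m[rep(1L, n), , drop = FALSE]
  o <- expand(o); h1 <- expand(h1); h2 <- expand(h2); solute <- expand(solute)
  sv <- solute - o
  if (!is.null(box)) sv <- min_image(sv, box)
  dip <- (h1 + h2) / 2 - o
  hh <- h2 - h1
  nsv <- sqrt(rowSums(sv^2)); ndip <- sqrt(rowSums(dip^2))
  if (any(nsv < 1e-9)) stop("solute point coincides with a water oxygen")
  if (any(ndip < 1e-9)) stop("zero-length dipole vector")
  theta <- .vec_angle(sv, dip)
  nrm <- .cross(sv, dip)
  nn <- sqrt(rowSums(nrm^2))
  ok <- nn > 1e-8 * nsv * ndip
  chi <- rep(NA_real_, n)
  if (any(ok)) chi[ok] <- .vec_angle(nrm[ok, , drop = FALSE], hh[ok, , drop = FALSE])
  data.frame(theta = theta, chi = chi, ok = ok)
}

#' Binned angular histogram over (theta, chi)
#'
#' Bin measure uses the exact integral of sin(theta) over each theta bin
#' (not a midpoint approximation), so closed-form uniform cases are exact.
#'
#' @param theta,chi angles in degrees in [0, 180].
#' @param grid `c(n_theta, n_chi)` bin counts (default `c(30, 30)`).
#' @return list with `counts` (matrix), `theta_edges`, `chi_edges` (degrees),
#'   `measure` (per-bin angular measure, radians), `c` (total measure),
#'   `n` (sample count).
#' @export
angular_histogram <- function(theta, chi, grid = c(30, 30)) {
  stopifnot(length(grid) == 2, all(grid >= 1))
  keep <- is.finite(theta) & is.finite(chi)
  theta <- theta[keep]; chi <- chi[keep]
  if (any(theta < 0 | theta > 180 | chi < 0 | chi > 180))
    stop("angles outside [0, 180] degrees")
  te <- seq(0, 180, length.out = grid[1] + 1)
  ce <- seq(0, 180, length.out = grid[2] + 1)
  ti <- pmin(pmax(findInterval(theta, te, rightmost.closed = TRUE), 1L), grid[1])
  ci <- pmin(pmax(findInterval(chi, ce, rightmost.closed = TRUE), 1L), grid[2])
  counts <- matrix(0, grid[1], grid[2])
  tab <- table(factor(ti, levels = seq_len(grid[1])),
               factor(ci, levels = seq_len(grid[2])))
  counts[] <- as.numeric(tab)
  dtheta_meas <- cos(.rad(te[-length(te)])) - cos(.rad(te[-1]))  # integral of sin
  dchi <- .rad(diff(ce))
  measure <- outer(dtheta_meas, dchi)
  list(counts = counts, theta_edges = te, chi_edges = ce,
       measure = measure, c = sum(measure), n = length(theta))
}

#' Rotational entropy from orientation samples
#'
#' Computes `T * S_Rot` from the binned `(theta, chi)` density relative to
#' the uniform orientational distribution. Empty bins contribute zero
#' (`0 * log 0 := 0`). The estimator is biased downward at finite n; the
#' bias vanishes as n grows.
#'
#' @param theta,chi angles in degrees.
#' @param grid `c(n_theta, n_chi)` bins (default `c(30, 30)`).
#' @param T temperature in kelvin (default 273).
#' @param min_samples minimum sample count required (default 1e4; lower it
#'   deliberately for toy inputs).
#' @return list with `TS_rot` (kcal/mol), `S_rot` (kcal/mol/K), `n`, and the
#'   histogram used.
#' @export
rotational_entropy <- function(theta, chi, grid = c(30, 30), T = 273,
                               min_samples = 1e4) {
  keep <- is.finite(theta) & is.finite(chi)
  n <- sum(keep)
  if (n == 0) stop("no orientation samples")
  if (n < min_samples)
    stop("only ", n, " samples (< min_samples = ", min_samples, ")")
  h <- angular_histogram(theta[keep], chi[keep], grid)
  if (any(h$measure <= 0)) stop("grid contains zero-measure bins")
  p_meas <- h$counts / h$n            # probability mass per bin
  dens <- p_meas / h$measure          # density w.r.t. sin(theta) dtheta dchi
  nz <- p_meas > 0
  S <- -.kB * sum(p_meas[nz] * log(dens[nz] * h$c))
  list(TS_rot = T * S, S_rot = S, n = h$n, T = T, grid = grid,
       c = h$c, histogram = h)
}

#' Translational entropy of a permuted water label's positions
#'
#' Voxel-histogram differential entropy of the 3-D position density over a
#' local bounding cell, referenced to the uniform density over that cell
#' (uniform occupancy gives exactly 0); reported as `T * S` in kcal/mol.
#' This construction is tagged `method: voxel-3D` in reports.
#'
#' @param pos `n x 3` matrix of one label's (permutation-reduced) positions.
#' @param bins voxel counts per axis (default `c(10, 10, 10)`).
#' @param T temperature in kelvin (default 273).
#' @param cell optional `2 x 3` matrix `rbind(lower, upper)` of the bounding
#'   cell; default is the data's bounding box.
#' @param min_samples minimum sample count (default 100).
#' @return list with `TS_trans` (kcal/mol), `S_trans`, `n`, `cell`, `method`.
#' @export
translational_entropy <- function(pos, bins = c(10, 10, 10), T = 273,
                                  cell = NULL, min_samples = 100) {
  pos <- rbind(pos)
  n <- nrow(pos)
  if (n < min_samples) stop("only ", n, " samples (< min_samples = ", min_samples, ")")
  if (is.null(cell)) cell <- rbind(apply(pos, 2, min), apply(pos, 2, max))
  widths <- cell[2, ] - cell[1, ]
  if (any(widths <= 0)) stop("degenerate cell (zero volume)")
  vox <- integer(n)
  mult <- c(1L, bins[1], bins[1] * bins[2])
  idx <- matrix(0L, n, 3)
  for (k in 1:3) {
    u <- (pos[, k] - cell[1, k]) / widths[k]
    idx[, k] <- pmin(pmax(floor(u * bins[k]), 0L), bins[k] - 1L)
  }
  vox <- idx %*% mult
  p <- tabulate(vox + 1L, nbins = prod(bins)) / n
  nz <- p > 0
  S <- -.kB * sum(p[nz] * log(p[nz] * prod(bins)))
  list(TS_trans = T * S, S_trans = S, n = n, T = T, cell = cell,
       bins = bins, method = "voxel-3D")
}

#' Per-water entropy profile, ranked ascending by rotational entropy
#'
#' For each tracked water label: the orientation series (under permutation
#' reduction) relative to its solute reference point, the resulting
#' `T*S_Rot`, and the voxel translational `T*S_Trans` of its permuted
#' positions. The solute reference point for each label is the site (by
#' default the nearest one at the reference frame) whose per-frame position
#' defines the O->solute vector.
#'
#' @param traj a `wtraj` object.
#' @param pmap a `perm_map` (or `NULL` for raw labels).
#' @param labels water labels to profile.
#' @param solute_sites integer vector of candidate solute atoms (e.g. IBS
#'   threonine hydroxyl oxygens, or a reference water's O for pure water).
#' @param T temperature in kelvin (default 273).
#' @param grid angular grid (default `c(30, 30)`).
#' @param trans_bins voxel grid for the translational part.
#' @param min_samples minimum orientation samples per label.
#' @return data.frame with columns `label`, `rank`, `n`, `n_flagged`,
#'   `TS_rot`, `TS_trans`, `solute_site`, sorted ascending by `TS_rot`.
#' @export
entropy_profile <- function(traj, pmap, labels, solute_sites, T = 273,
                            grid = c(30, 30), trans_bins = c(8, 8, 8),
                            min_samples = 1) {
  nf <- n_frames(traj)
  ref <- if (is.null(pmap)) 1L else pmap$reference_frame
  box_ref <- traj$box[, , ref]
  rows <- lapply(labels, function(lab) {
    o_ref <- traj$coords[traj$waters$O[lab], , ref]
    dsites <- vapply(solute_sites, function(s)
      sqrt(sum(min_image(traj$coords[s, , ref] - o_ref, box_ref)^2)), numeric(1))
    site <- solute_sites[which.min(dsites)]
    o <- permuted_coords(traj, pmap, lab, "O")
    h1 <- permuted_coords(traj, pmap, lab, "H1")
    h2 <- permuted_coords(traj, pmap, lab, "H2")
    sol <- t(vapply(seq_len(nf), function(f) traj$coords[site, , f], numeric(3)))
    ang <- orientation_angles(o, h1, h2, sol, box = traj$box[, , 1])
    if (!any(ang$ok))
      return(data.frame(label = lab, n = 0L, n_flagged = sum(!ang$ok),
                        TS_rot = NA_real_, TS_trans = NA_real_,
                        solute_site = site))
    rot <- rotational_entropy(ang$theta[ang$ok], ang$chi[ang$ok], grid = grid,
                              T = T, min_samples = min_samples)
    trans <- tryCatch(
      translational_entropy(o, bins = trans_bins, T = T,
                            min_samples = min(min_samples, nf)),
      error = function(e) list(TS_trans = NA_real_))
    data.frame(label = lab, n = rot$n, n_flagged = sum(!ang$ok),
               TS_rot = rot$TS_rot, TS_trans = trans$TS_trans,
               solute_site = site)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$TS_rot, out$label), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("label", "rank", "n", "n_flagged", "TS_rot", "TS_trans", "solute_site")]
}
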