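## Water-structure order metrics: O-O-O angle distributions around selected
## central waters, and the conditional tetrahedral order parameter t_h for
## central waters with 2 to 4 neighbors:
##
##   t_h = 1 - (9/4) * (1/n_p) * sum_pairs (cos psi + 1/3)^2
##
## with n_p = k(k-1)/2 angle pairs among the k nearest neighbor oxygens.
## The per-pair normalization fixes t_h = 1 for perfect tetrahedral angles
## and E[t_h] = 0 for isotropic neighbor directions at every k, so values
## are comparable across k; the k = 4 case coincides with the standard
## Errington-Debenedetti q.

#' Conditional tetrahedral order parameter from neighbor vectors
#'
#' @param vecs `k x 3` matrix of vectors from a central oxygen to its
#'   neighbor oxygens, `2 <= k <= 4`.
#' @return scalar t_h (at most 1).
#' @export
tetrahedral_order <- function(vecs) {
  vecs <- rbind(vecs)
  k <- nrow(vecs)
  if (k < 2L || k > 4L) stop("need 2 to 4 neighbor vectors, got ", k)
  u <- vecs / sqrt(rowSums(vecs^2))
  cosps <- (u %*% t(u))[upper.tri(diag(k))]
  1 - (9 / 4) * mean((cosps + 1 / 3)^2)
}

## neighbor O indices (nearest-first) of point `x` among water oxygens,
## within r_neighbor, excluding `exclude` atom ids
.water_neighbors <- function(traj, frame, x, r_neighbor, exclude = integer()) {
  box <- traj$box[, , frame]
  ows <- setdiff(traj$waters$O, exclude)
  om <- traj$coords[ows, , frame, drop = FALSE][, , 1, drop = TRUE]
  om <- rbind(om)
  d <- min_image(sweep(om, 2, x), box)
  r <- sqrt(rowSums(d^2))
  sel <- which(r <= r_neighbor & r > 1e-9)
  sel <- sel[order(r[sel])]
  list(idx = ows[sel], vecs = d[sel, , drop = FALSE], r = r[sel])
}

#' O-O-O angle distribution around threonine-adjacent central waters
#'
#' Each frame, the water O nearest each site (e.g. a threonine hydroxyl
#' oxygen) is taken as a central water; every pair of neighbor water oxygens
#' within `r_neighbor` subtends one angle at the central O. Angles are
#' histogrammed over frames as a normalized density. A peak near 109
#' degrees signals tetrahedral (ice-like) ordering.
#'
#' @param traj a `wtraj` object.
#' @param sites site atom indices whose nearest waters act as centrals; or
#'   `NULL` with explicit `central_labels`.
#' @param r_neighbor neighbor cutoff in Angstrom (default 3.5).
#' @param bin histogram bin width in degrees (default 1).
#' @param central_labels optional fixed water ids to use as centrals each
#'   frame instead of nearest-to-site selection.
#' @return list with `breaks`, `mids`, `density` (integrates to 1 over
#'   degrees), `n` angle samples, `mode` (degrees, midpoint of the maximal
#'   bin), `n_skipped` centrals with fewer than 2 neighbors.
#' @export
ooo_angle_distribution <- function(traj, sites = NULL, r_neighbor = 3.5,
                                   bin = 1, central_labels = NULL) {
  angles <- numeric(0)
  n_skipped <- 0L
  for (f in seq_len(n_frames(traj))) {
    if (is.null(central_labels)) {
      cent <- vapply(sites, function(s) {
        nb <- .water_neighbors(traj, f, traj$coords[s, , f], Inf)
        nb$idx[1]
      }, numeric(1))
    } else {
      cent <- traj$waters$O[central_labels]
    }
    for (co in unique(cent)) {
      nb <- .water_neighbors(traj, f, traj$coords[co, , f], r_neighbor,
                             exclude = co)
      k <- nrow(nb$vecs)
      if (k < 2L) { n_skipped <- n_skipped + 1L; next }
      u <- nb$vecs / sqrt(rowSums(nb$vecs^2))
      cosps <- (u %*% t(u))[upper.tri(diag(k))]
      angles <- c(angles, .deg(acos(pmin(1, pmax(-1, cosps)))))
    }
  }
  ## bins centered on whole degrees so the mode reports at integer angles
  breaks <- seq(-bin / 2, 180 + bin / 2, by = bin)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  dens <- h$counts / sum(h$counts) / diff(breaks)
  list(breaks = breaks, mids = h$mids, density = dens, n = length(angles),
       mode = h$mids[which.max(h$counts)], n_skipped = n_skipped)
}

#' Conditional tetrahedral order parameter for tracked waters
#'
#' Per frame and label, t_h from the 2-4 nearest water oxygens within
#' `r_neighbor` of the label's O (threonine oxygens are never counted as
#' neighbors). Centrals with fewer than 2 neighbors are excluded and
#' counted.
#'
#' @param traj a `wtraj` object.
#' @param labels water labels (typically the H-bonded-to-threonine set).
#' @param r_neighbor neighbor cutoff in Angstrom (default 3.5).
#' @param pmap optional `perm_map` for label tracking.
#' @return list with `values` (data.frame: `label`, `frame`, `k`, `t_h`),
#'   `per_label` (data.frame: `label`, `mean_t_h`, `n`), `n_excluded`.
#' @export
conditional_tetrahedral <- function(traj, labels, r_neighbor = 3.5,
                                    pmap = NULL) {
  rows <- list(); n_excl <- 0L
  for (f in seq_len(n_frames(traj))) {
    ids <- if (is.null(pmap)) labels else pmap$perm[f, labels]
    for (j in seq_along(labels)) {
      co <- traj$waters$O[ids[j]]
      nb <- .water_neighbors(traj, f, traj$coords[co, , f], r_neighbor,
                             exclude = co)
      k <- min(nrow(nb$vecs), 4L)
      if (k < 2L) { n_excl <- n_excl + 1L; next }
      th <- tetrahedral_order(nb$vecs[seq_len(k), , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(label = labels[j], frame = f,
                                              k = k, t_h = th)
    }
  }
  values <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), frame = integer(), k = integer(),
               t_h = numeric())
  per_label <- if (nrow(values)) {
    agg <- aggregate(t_h ~ label, values, mean)
    cnt <- aggregate(t_h ~ label, values, length)
    data.frame(label = agg$label, mean_t_h = agg$t_h, n = cnt$t_h)
  } else data.frame(label = integer(), mean_t_h = numeric(), n = integer())
  list(values = values, per_label = per_label, n_excluded = n_excl)
}
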