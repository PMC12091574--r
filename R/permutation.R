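## Permutation reduction: per-frame relabeling of indistinguishable waters
## against a reference configuration, minimizing the total squared
## minimum-image O-O displacement.  Each label then occupies a localized
## spatial slot, which is what makes per-water statistics meaningful.

## squared minimum-image O-O distance matrix: rows = reference labels,
## columns = frame waters
.cost_matrix <- function(ref_o, frame_o, box) {
  n <- nrow(ref_o)
  cost <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    d <- sweep(frame_o, 2, ref_o[i, ])
    cost[i, ] <- rowSums(min_image(d, box)^2)
  }
  cost
}

#' Relabel one frame's waters against a reference configuration
#'
#' Solves the linear assignment problem minimizing the summed squared
#' minimum-image O-O displacement between reference water positions and the
#' frame's water positions. Orientation is free: only oxygen positions enter
#' the cost.
#'
#' @param frame_o `n x 3` matrix of water O positions in the frame.
#' @param ref_o `n x 3` matrix of reference water O positions.
#' @param box `3 x 3` lattice-vector matrix for the frame.
#' @return list with `perm` (integer; `perm[label]` is the frame water
#'   occupying that reference label), `cost` (optimal total squared
#'   displacement, Angstrom^2) and `identity_cost`.
#' @export
relabel_frame <- function(frame_o, ref_o, box) {
  frame_o <- rbind(frame_o); ref_o <- rbind(ref_o)
  if (nrow(frame_o) != nrow(ref_o)) stop("mismatched water counts")
  cost <- .cost_matrix(ref_o, frame_o, box)
  perm <- as.integer(solve_assignment(cost))
  total <- sum(cost[cbind(seq_len(nrow(cost)), perm)])
  list(perm = perm, cost = total, identity_cost = sum(diag(cost)))
}

#' Permutation-reduce a whole trajectory
#'
#' Applies [relabel_frame()] to every frame against a fixed reference frame,
#' producing per-frame label maps that downstream per-water series index
#' through. The optimal cost never exceeds the identity cost, so each label
#' stays in a localized region around its reference slot.
#'
#' @param traj a `wtraj` object.
#' @param reference_frame frame defining the reference configuration
#'   (default 1, recorded in the result).
#' @return object of class `perm_map`: list with `perm`
#'   (`n_frames x n_waters` integer matrix), `costs`, `identity_costs`,
#'   `reference_frame`.
#' @export
permute_trajectory <- function(traj, reference_frame = 1L) {
  nf <- n_frames(traj)
  nw <- n_waters(traj)
  ref_o <- traj$coords[traj$waters$O, , reference_frame, drop = FALSE][, , 1]
  perm <- matrix(NA_integer_, nf, nw)
  costs <- numeric(nf); idc <- numeric(nf)
  for (f in seq_len(nf)) {
    fo <- traj$coords[traj$waters$O, , f, drop = FALSE][, , 1]
    r <- relabel_frame(fo, ref_o, traj$box[, , f])
    perm[f, ] <- r$perm
    costs[f] <- r$cost
    idc[f] <- r$identity_cost
  }
  structure(list(perm = perm, costs = costs, identity_costs = idc,
                 reference_frame = reference_frame),
            class = "perm_map")
}

#' @export
print.perm_map <- function(x, ...) {
  cat(sprintf("<perm_map> %d frames x %d labels (reference frame %d)\n",
              nrow(x$perm), ncol(x$perm), x$reference_frame))
  cat(sprintf("  mean cost %.3f A^2 (identity %.3f A^2)\n",
              mean(x$costs), mean(x$identity_costs)))
  invisible(x)
}

## water id occupying `label` at each frame (identity map when pmap NULL)
.label_series <- function(pmap, label, nf) {
  if (is.null(pmap)) rep.int(label, nf) else pmap$perm[, label]
}

#' Per-label atom coordinate series under permutation reduction
#'
#' @param traj a `wtraj` object.
#' @param pmap a `perm_map` from [permute_trajectory()], or `NULL` for raw
#'   (unpermuted) labels.
#' @param label water label (reference-frame water id).
#' @param atom one of `"O"`, `"H1"`, `"H2"`.
#' @return `n_frames x 3` matrix of positions, Angstrom.
#' @export
permuted_coords <- function(traj, pmap, label, atom = "O") {
  stopifnot(atom %in% c("O", "H1", "H2"))
  nf <- n_frames(traj)
  ids <- .label_series(pmap, label, nf)
  ai <- traj$waters[[atom]][ids]
  out <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf)) out[f, ] <- traj$coords[ai[f], , f]
  out
}

#' Write per-frame permutation costs to CSV
#'
#' @param pmap a `perm_map`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_permutation_costs <- function(pmap, path) {
  write.csv(data.frame(frame = seq_along(pmap$costs), cost = pmap$costs,
                       identity_cost = pmap$identity_costs),
            path, row.names = FALSE)
  invisible(path)
}
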