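## Geometric hydrogen-bond detection and per-water H-bond statistics.
##
## A donor O-H ... acceptor O pair is bonded when the donor-O to acceptor-O
## minimum-image distance is within r_cut and the deviation angle between
## the O_d -> H and O_d -> O_a vectors is within angle_cut (the common
## trajectory-analysis convention for "O-H...O angle within 30 degrees").
## The alternative convention (angle at the hydrogen >= 180 - angle_cut) is
## available through the criterion's angle-definition tag.

#' Hydrogen-bond criterion
#'
#' @param r_cut donor-O to acceptor-O distance cutoff in Angstrom
#'   (default 3.5).
#' @param angle_cut angular cutoff in degrees (default 30). For the
#'   residence-time reactant definition use 35.
#' @param angle_def `"deviation"` (angle between O_d->H and O_d->O_a, the
#'   default) or `"dha"` (donor-hydrogen-acceptor angle at H must be at
#'   least `180 - angle_cut`).
#' @return an object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(r_cut = 3.5, angle_cut = 30,
                            angle_def = c("deviation", "dha")) {
  angle_def <- match.arg(angle_def)
  if (r_cut <= 0) stop("r_cut must be positive")
  if (angle_cut <= 0 || angle_cut >= 90) stop("angle_cut must be in (0, 90)")
  structure(list(r_cut = r_cut, angle_cut = angle_cut, angle_def = angle_def),
            class = "hbond_criterion")
}

#' Donor table for water molecules
#'
#' One row per O-H bond (two per water).
#'
#' @param traj a `wtraj` object.
#' @param labels water ids to include (default all).
#' @return data.frame with columns `O`, `H` (atom indices).
#' @export
water_donors <- function(traj, labels = NULL) {
  w <- traj$waters
  if (!is.null(labels)) w <- w[labels, , drop = FALSE]
  data.frame(O = c(w$O, w$O), H = c(w$H1, w$H2))
}

#' Detect hydrogen bonds in one frame
#'
#' All donor-acceptor pairs satisfying the distance and angle cutoffs under
#' minimum-image geometry.
#'
#' @param traj a `wtraj` object.
#' @param frame frame index.
#' @param donors data.frame with columns `O`, `H` (one row per O-H bond);
#'   see [water_donors()].
#' @param acceptors integer vector of acceptor O atom indices.
#' @param criterion an [hbond_criterion()].
#' @return data.frame with columns `frame`, `donor_o`, `h`, `acceptor_o`,
#'   `distance`, `angle`.
#' @export
detect_hbonds <- function(traj, frame, donors, acceptors,
                          criterion = hbond_criterion()) {
  if (nrow(donors) == 0L || length(acceptors) == 0L)
    return(data.frame(frame = integer(), donor_o = integer(), h = integer(),
                      acceptor_o = integer(), distance = numeric(),
                      angle = numeric()))
  if (any(is.na(donors$H))) {
    bad <- donors$O[which(is.na(donors$H))[1]]
    stop("donor atom ", bad, " has no hydrogen")
  }
  box <- traj$box[, , frame]
  xyz <- traj$coords[, , frame]
  nd <- nrow(donors); na_ <- length(acceptors)
  di <- rep(seq_len(nd), times = na_)
  ai <- rep(acceptors, each = nd)
  sel <- donors$O[di] != ai
  di <- di[sel]; ai <- ai[sel]
  doa <- min_image(xyz[ai, , drop = FALSE] - xyz[donors$O[di], , drop = FALSE], box)
  r <- sqrt(rowSums(doa^2))
  near <- r <= criterion$r_cut
  di <- di[near]; ai <- ai[near]; doa <- doa[near, , drop = FALSE]; r <- r[near]
  if (length(di) == 0L)
    return(data.frame(frame = integer(), donor_o = integer(), h = integer(),
                      acceptor_o = integer(), distance = numeric(),
                      angle = numeric()))
  oh <- min_image(xyz[donors$H[di], , drop = FALSE] - xyz[donors$O[di], , drop = FALSE], box)
  if (criterion$angle_def == "deviation") {
    ang <- .vec_angle(oh, doa)
    ok <- ang <= criterion$angle_cut
  } else {
    ho <- -oh
    ha <- min_image(xyz[ai, , drop = FALSE] - xyz[donors$H[di], , drop = FALSE], box)
    ang <- .vec_angle(ho, ha)
    ok <- ang >= 180 - criterion$angle_cut
  }
  data.frame(frame = rep.int(frame, sum(ok)), donor_o = donors$O[di][ok],
             h = donors$H[di][ok], acceptor_o = ai[ok],
             distance = r[ok], angle = ang[ok])
}

## per-frame bonded incidence involving each label's water O, given partner
## donors/acceptors; returns counts (donated + accepted) per label
.label_hbond_counts <- function(traj, frame, label_ids, partner_donors,
                                partner_acceptors, criterion) {
  w <- traj$waters
  own_donors <- data.frame(O = c(w$O[label_ids], w$O[label_ids]),
                           H = c(w$H1[label_ids], w$H2[label_ids]))
  own_o <- w$O[label_ids]
  donated <- detect_hbonds(traj, frame, own_donors, partner_acceptors, criterion)
  accepted <- detect_hbonds(traj, frame, partner_donors, own_o, criterion)
  cnt_d <- table(factor(donated$donor_o, levels = own_o))
  cnt_a <- table(factor(accepted$acceptor_o, levels = own_o))
  as.numeric(cnt_d) + as.numeric(cnt_a)
}

#' Mean hydrogen-bond count per tracked water
#'
#' Mean over frames of (donated + accepted) bonds per label, counting bonds
#' to the supplied partner set (water-water and, in the IBS context,
#' water-threonine-oxygen bonds). Which partners are included is explicit:
#' for a pure-water baseline pass only waters; for an IBS analysis add the
#' hydroxyl donors and acceptor oxygens.
#'
#' @param traj a `wtraj` object.
#' @param labels water labels to score.
#' @param criterion an [hbond_criterion()].
#' @param pmap optional `perm_map`; when supplied, labels are tracked
#'   through permutation reduction.
#' @param partner_donors data.frame(`O`, `H`) of partner donor bonds;
#'   default: all waters in `traj`.
#' @param partner_acceptors acceptor O indices; default: all water oxygens.
#' @return named numeric vector of per-label mean counts.
#' @export
avg_hbonds_per_water <- function(traj, labels, criterion = hbond_criterion(),
                                 pmap = NULL,
                                 partner_donors = water_donors(traj),
                                 partner_acceptors = traj$waters$O) {
  if (length(labels) == 0L) stop("empty label set")
  nf <- n_frames(traj)
  acc <- matrix(0, nf, length(labels))
  for (f in seq_len(nf)) {
    ids <- if (is.null(pmap)) labels else pmap$perm[f, labels]
    ## partners must not include the label's own atoms: handled by the
    ## detector's self-pair exclusion plus double-count removal below
    cnt <- .label_hbond_counts(traj, f, ids, partner_donors,
                               partner_acceptors, criterion)
    acc[f, ] <- cnt
  }
  setNames(colMeans(acc), paste0("w", labels))
}

#' Waters persistently hydrogen-bonded to hydroxyl groups
#'
#' Selects the labels whose fraction of frames H-bonded (in either donor
#' direction) to any of the listed hydroxyls is at least `occupancy_min`.
#'
#' @param traj a `wtraj` object.
#' @param hydroxyls list with `O` (hydroxyl oxygen atom indices) and `H`
#'   (their hydroxyl hydrogens, same order).
#' @param criterion an [hbond_criterion()].
#' @param occupancy_min minimum bonded-frame fraction (default 0.5).
#' @param pmap optional `perm_map` for label tracking.
#' @param labels candidate labels (default all waters).
#' @return data.frame with columns `label`, `occupancy`, filtered to
#'   `occupancy >= occupancy_min`, ordered by decreasing occupancy.
#' @export
waters_hbonded_to_hydroxyls <- function(traj, hydroxyls,
                                        criterion = hbond_criterion(),
                                        occupancy_min = 0.5, pmap = NULL,
                                        labels = seq_len(n_waters(traj))) {
  if (length(hydroxyls$O) == 0L) stop("empty hydroxyl site set")
  nf <- n_frames(traj)
  hyd_donors <- data.frame(O = hydroxyls$O, H = hydroxyls$H)
  bonded <- matrix(FALSE, nf, length(labels))
  w <- traj$waters
  for (f in seq_len(nf)) {
    ids <- if (is.null(pmap)) labels else pmap$perm[f, labels]
    own_donors <- data.frame(O = c(w$O[ids], w$O[ids]),
                             H = c(w$H1[ids], w$H2[ids]))
    donated <- detect_hbonds(traj, f, own_donors, hydroxyls$O, criterion)
    accepted <- detect_hbonds(traj, f, hyd_donors, w$O[ids], criterion)
    hit_o <- unique(c(donated$donor_o, accepted$acceptor_o))
    bonded[f, ] <- w$O[ids] %in% hit_o
  }
  occ <- colMeans(bonded)
  out <- data.frame(label = labels, occupancy = occ)
  out <- out[out$occupancy >= occupancy_min, , drop = FALSE]
  out[order(-out$occupancy, out$label), ]
}
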