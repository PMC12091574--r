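## Trajectory container and periodic-boundary geometry.
##
## Internal units are Angstrom and picosecond everywhere; the GRO reader and
## writer convert from/to nm at the boundary.  A trajectory is a list with
##   coords : n_atoms x 3 x n_frames array (Angstrom)
##   box    : 3 x 3 x n_frames array, rows are the lattice vectors a, b, c
##   times  : frame times (ps), strictly increasing, uniform spacing
##   atoms  : data.frame(name, resname, resid)
##   waters : data.frame(resid, O, H1, H2) -- atom indices per water molecule

#' Construct a trajectory object
#'
#' Builds the in-memory trajectory model used by every analysis stage. Water
#' molecules are auto-detected from residue names; each must contain exactly
#' one oxygen and at least two hydrogens (extra sites such as TIP5P lone
#' pairs are carried in the coordinates but ignored by all geometric
#' criteria).
#'
#' @param coords numeric array `n_atoms x 3 x n_frames`, Angstrom.
#' @param box `3 x 3` matrix or `3 x 3 x n_frames` array of lattice vectors
#'   (rows), Angstrom.
#' @param atoms data.frame with columns `name`, `resname`, `resid`.
#' @param dt frame spacing in ps (default 0.1 ps).
#' @param times optional explicit frame times (ps); default `0, dt, 2*dt, ...`.
#' @param water_residues residue names treated as water.
#' @return an object of class `wtraj`.
#' @export
new_trajectory <- function(coords, box, atoms, dt = 0.1,
                           times = NULL,
                           water_residues = c("SOL", "HOH", "WAT", "TIP5", "TIP3", "TIP4", "SPC")) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (n_frames < 1L) stop("trajectory has zero frames")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (length(dim(box)) == 2L) box <- array(box, c(3L, 3L, n_frames))
  stopifnot(all(dim(box) == c(3L, 3L, n_frames)))
  for (f in seq_len(n_frames)) {
    if (det(box[, , f]) <= 0) stop("degenerate box (volume <= 0) at frame ", f)
  }
  if (nrow(atoms) != n_atoms) stop("atom table does not match coordinate count")
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * dt
  if (n_frames > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    if (max(abs(dts - dt)) > 1e-6) stop("non-uniform frame spacing (tolerance 1e-6 ps)")
  }
  waters <- detect_waters(atoms, coords[, , 1, drop = FALSE][, , 1], water_residues)
  structure(list(coords = coords, box = box, times = times, dt = dt,
                 atoms = atoms, waters = waters),
            class = "wtraj")
}

#' @export
print.wtraj <- function(x, ...) {
  cat(sprintf("<wtraj> %d atoms, %d frames (dt = %g ps), %d waters\n",
              dim(x$coords)[1], dim(x$coords)[3], x$dt, nrow(x$waters)))
  invisible(x)
}

#' Number of frames / waters in a trajectory
#' @param traj a `wtraj` object.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_waters <- function(traj) nrow(traj$waters)

.element_of <- function(name) {
  toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", name))
}

## Water detection: group by (resname, resid); exactly one O and >= 2 H per
## residue; first two hydrogens by atom-table order after sorting names, so
## the result is invariant to atom ordering within the residue.
detect_waters <- function(atoms, coords1, water_residues) {
  is_w <- atoms$resname %in% water_residues
  if (!any(is_w)) stop("no waters detected (residue names checked: ",
                       paste(water_residues, collapse = ", "), ")")
  idx <- which(is_w)
  key <- paste(atoms$resname[idx], atoms$resid[idx])
  groups <- split(idx, factor(key, levels = unique(key)))
  rows <- lapply(groups, function(g) {
    el <- .element_of(atoms$name[g])
    o <- g[el == "O"]
    h <- g[el == "H"]
    if (length(o) != 1L || length(h) < 2L)
      stop("malformed water residue ", atoms$resid[g[1]],
           " (need exactly 1 O and >= 2 H)")
    h <- h[order(atoms$name[h])][1:2]
    data.frame(resid = atoms$resid[o], O = o, H1 = h[1], H2 = h[2])
  })
  waters <- do.call(rbind, rows)
  rownames(waters) <- NULL
  d1 <- sqrt(rowSums((coords1[waters$H1, , drop = FALSE] - coords1[waters$O, , drop = FALSE])^2))
  d2 <- sqrt(rowSums((coords1[waters$H2, , drop = FALSE] - coords1[waters$O, , drop = FALSE])^2))
  if (any(d1 < 0.8 | d1 > 1.2 | d2 < 0.8 | d2 > 1.2))
    stop("O-H distances outside 0.8-1.2 A in first frame; wrong unit or topology?")
  waters
}

## ---- minimum image ---------------------------------------------------------

#' Minimum-image displacement vectors
#'
#' Applies the minimum-image convention for an (orthorhombic or reduced
#' triclinic) periodic box to a batch of raw displacement vectors.
#'
#' @param d numeric `m x 3` matrix (or single 3-vector) of displacements, Angstrom.
#' @param box `3 x 3` lattice-vector matrix (rows are box vectors).
#' @return `m x 3` matrix of minimum-image displacements.
#' @export
min_image <- function(d, box) {
  d <- rbind(d)
  if (det(box) <= 0) stop("degenerate box (volume <= 0)")
  min_image_cpp(d, box, solve(box))
}

#' Minimum-image displacement between two atoms in a frame
#'
#' @param traj a `wtraj` object.
#' @param i,j atom indices; the displacement points from `i` to `j`.
#' @param frame frame index (default 1).
#' @return length-3 numeric vector, Angstrom.
#' @export
minimum_image_vector <- function(traj, i, j, frame = 1L) {
  na <- dim(traj$coords)[1]
  if (any(c(i, j) < 1L) || any(c(i, j) > na)) stop("atom index out of range")
  d <- traj$coords[j, , frame] - traj$coords[i, , frame]
  drop(min_image(d, traj$box[, , frame]))
}

## minimum-image distances from one point to many points
.mi_dist <- function(from, to_mat, box) {
  d <- sweep(rbind(to_mat), 2, from)
  sqrt(rowSums(min_image(d, box)^2))
}

## ---- selections ------------------------------------------------------------

#' Select the k waters nearest to a site set
#'
#' Distance of a water is the minimum over all site atoms of the
#' minimum-image O-to-site distance, evaluated at a single reference frame.
#' Ties are broken by water id. The selection is made once; downstream
#' per-water statistics track these labels through permutation reduction.
#'
#' @param traj a `wtraj` object.
#' @param sites integer vector of site atom indices (e.g. threonine
#'   hydroxyl oxygens or C-alpha atoms of an ice-binding surface).
#' @param k number of waters to select (`k <= n_waters(traj)`).
#' @param frame reference frame for the ranking (default 1).
#' @return integer vector of `k` water ids ordered nearest-first.
#' @export
nearest_waters <- function(traj, sites, k, frame = 1L) {
  nw <- n_waters(traj)
  if (k > nw) stop("k exceeds the number of waters (", nw, ")")
  if (length(sites) == 0L) stop("empty site set")
  box <- traj$box[, , frame]
  ow <- traj$coords[traj$waters$O, , frame, drop = FALSE][, , 1]
  dmin <- rep(Inf, nw)
  for (s in sites) {
    dmin <- pmin(dmin, .mi_dist(traj$coords[s, , frame], ow, box))
  }
  order(dmin, seq_len(nw))[seq_len(k)]
}

#' Site-water radial distribution function
#'
#' Shell-volume-normalized g(r) of water oxygens around a site set, averaged
#' over frames and sites. Used to choose the product-state distance cutoff of
#' the residence-time analysis (the first solvation minimum).
#'
#' @param traj a `wtraj` object.
#' @param sites integer vector of site atom indices.
#' @param r_max maximum radius (Angstrom); must be below half the smallest
#'   box extent.
#' @param dr bin width (Angstrom).
#' @return data.frame with columns `r` (bin centers), `g`, `count`.
#' @export
site_water_rdf <- function(traj, sites, r_max, dr) {
  if (dr <= 0) stop("dr must be positive")
  if (length(sites) == 0L) stop("empty site set")
  half_min <- min(apply(traj$box, 3, function(b) min(sqrt(rowSums(b^2))))) / 2
  if (r_max >= half_min) stop("r_max must be below half the smallest box dimension")
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1L)
  nf <- n_frames(traj)
  vol <- 0
  for (f in seq_len(nf)) {
    box <- traj$box[, , f]
    vol <- vol + det(box)
    ow <- traj$coords[traj$waters$O, , f, drop = FALSE][, , 1]
    for (s in sites) {
      d <- .mi_dist(traj$coords[s, , f], ow, box)
      d <- d[d > 1e-9 & d < r_max]
      counts <- counts + graphics::hist(d, breaks = edges, plot = FALSE)$counts
    }
  }
  vol <- vol / nf
  rho <- n_waters(traj) / vol
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  norm <- nf * length(sites) * rho * shell
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
             g = counts / norm, count = counts)
}

## ---- file I/O --------------------------------------------------------------

#' Load a trajectory from standard MD file formats
#'
#' Supports PDB (single- or multi-model) and GRO (single- or multi-frame)
#' topologies, and multi-model PDB, multi-frame GRO or DCD trajectories.
#' GRO coordinates are converted from nm to Angstrom on read. XTC is a
#' compressed binary format without a reader in this toolchain and is
#' rejected with a clear error.
#'
#' @param topology path to a PDB or GRO file defining atoms (and, for a
#'   single-file trajectory, the frames).
#' @param trajectory optional path to a multi-frame file (PDB/GRO/DCD).
#' @param dt frame spacing in ps used when the format carries no times
#'   (default 0.1 ps).
#' @param water_residues residue names treated as water.
#' @return a `wtraj` object.
#' @export
load_trajectory <- function(topology, trajectory = NULL, dt = 0.1,
                            water_residues = c("SOL", "HOH", "WAT", "TIP5", "TIP3", "TIP4", "SPC")) {
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  ext <- function(p) tolower(tools::file_ext(p))
  top <- switch(ext(topology),
    gro = .read_gro(topology),
    pdb = .read_pdb(topology),
    stop("unsupported topology format: .", ext(topology), " (use PDB or GRO)"))
  if (is.null(trajectory)) {
    return(new_trajectory(top$coords, top$box, top$atoms, dt = dt,
                          water_residues = water_residues))
  }
  if (!file.exists(trajectory)) stop("trajectory file not found: ", trajectory)
  trj <- switch(ext(trajectory),
    gro = .read_gro(trajectory),
    pdb = .read_pdb(trajectory),
    dcd = .read_dcd(trajectory, top),
    xtc = ,
    trr = stop("unsupported trajectory format: .", ext(trajectory),
               " (compressed GROMACS binaries are not readable here; ",
               "convert to DCD, multi-frame GRO or multi-model PDB)"),
    stop("unsupported trajectory format: .", ext(trajectory)))
  if (dim(trj$coords)[1] != nrow(top$atoms))
    stop("atom count mismatch between topology (", nrow(top$atoms),
         ") and trajectory (", dim(trj$coords)[1], ")")
  new_trajectory(trj$coords, trj$box, top$atoms, dt = dt,
                 water_residues = water_residues)
}

## GRO format: fixed columns, coordinates in nm.
.read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); atoms <- NULL
  i <- 1L; nf <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop("malformed GRO file at line ", i + 1L, " (frame ", nf + 1L, ")")
    if (i + 1L + n + 1L > length(lines))
      stop("truncated GRO frame ", nf + 1L)
    al <- lines[(i + 2L):(i + 1L + n)]
    xyz <- cbind(as.numeric(substr(al, 21, 28)),
                 as.numeric(substr(al, 29, 36)),
                 as.numeric(substr(al, 37, 44))) * 10
    if (any(is.na(xyz))) stop("unreadable coordinates in GRO frame ", nf + 1L)
    if (is.null(atoms)) {
      atoms <- data.frame(name = trimws(substr(al, 11, 15)),
                          resname = trimws(substr(al, 6, 10)),
                          resid = as.integer(substr(al, 1, 5)))
    } else if (n != nrow(atoms)) {
      stop("inconsistent atom count at frame ", nf + 1L)
    }
    bv <- as.numeric(strsplit(trimws(lines[i + 1L + n + 1L]), "\\s+")[[1]]) * 10
    box <- diag(3)
    if (length(bv) >= 3) { box <- diag(bv[1:3]) }
    if (length(bv) == 9) {
      box[1, 2] <- bv[4]; box[1, 3] <- bv[5]
      box[2, 1] <- bv[6]; box[2, 3] <- bv[7]
      box[3, 1] <- bv[8]; box[3, 2] <- bv[9]
    }
    nf <- nf + 1L
    frames[[nf]] <- xyz; boxes[[nf]] <- box
    i <- i + 1L + n + 2L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (nf == 0L) stop("zero frames in GRO file: ", path)
  coords <- array(unlist(frames), c(nrow(atoms), 3L, nf))
  box <- array(unlist(boxes), c(3L, 3L, nf))
  list(coords = coords, box = box, atoms = atoms)
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Coordinates are written in nm per the format convention.
#'
#' @param traj a `wtraj` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  atoms <- traj$atoms
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f] / 10
    writeLines(sprintf("frame t=%.4f ps", traj$times[f]), con)
    writeLines(sprintf("%5d", nrow(atoms)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       atoms$resid %% 100000L, atoms$resname, atoms$name,
                       seq_len(nrow(atoms)) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    b <- traj$box[, , f] / 10
    if (all(abs(b[upper.tri(b) | lower.tri(b)]) < 1e-9)) {
      writeLines(sprintf("%10.5f%10.5f%10.5f", b[1, 1], b[2, 2], b[3, 3]), con)
    } else {
      writeLines(paste(sprintf("%10.5f", c(b[1, 1], b[2, 2], b[3, 3],
                                           b[1, 2], b[1, 3], b[2, 1],
                                           b[2, 3], b[3, 1], b[3, 2])),
                       collapse = ""), con)
    }
  }
  invisible(path)
}

.cell_to_box <- function(a, b, c, alpha, beta, gamma) {
  al <- .rad(alpha); be <- .rad(beta); ga <- .rad(gamma)
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(ga), b * sin(ga), 0)
  cx <- c * cos(be)
  cy <- c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(0, c^2 - cx^2 - cy^2))
  rbind(v1, v2, c(cx, cy, cz), deparse.level = 0)
}

.read_pdb <- function(path) {
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  cl <- grep("^CRYST1", readLines(path, n = 2000), value = TRUE)
  if (length(cl) >= 1) {
    v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                      substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
    box <- .cell_to_box(v[1], v[2], v[3], v[4], v[5], v[6])
  } else {
    warning("no CRYST1 record in ", path, "; assuming a 1000 A cubic box")
    box <- diag(1000, 3)
  }
  atoms <- data.frame(name = p$atom$elety, resname = p$atom$resid,
                      resid = p$atom$resno)
  list(coords = coords, box = array(box, c(3, 3, nf)), atoms = atoms)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Emits one MODEL per frame plus a CRYST1 record from the first frame's box.
#'
#' @param traj a `wtraj` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  xyz <- t(apply(traj$coords, 3, function(m) as.numeric(t(m))))
  if (n_frames(traj) == 1L) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = traj$atoms$resid, resid = traj$atoms$resname,
                   elety = traj$atoms$name)
  cell <- .box_to_cell(traj$box[, , 1])
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])
  writeLines(c(cryst, readLines(path)), path)
  invisible(path)
}

.box_to_cell <- function(box) {
  a <- sqrt(sum(box[1, ]^2)); b <- sqrt(sum(box[2, ]^2)); cc <- sqrt(sum(box[3, ]^2))
  al <- .vec_angle(box[2, ], box[3, ]); be <- .vec_angle(box[1, ], box[3, ])
  ga <- .vec_angle(box[1, ], box[2, ])
  c(a, b, cc, al, be, ga)
}

.read_dcd <- function(path, top) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  list(coords = coords, box = array(top$box[, , 1], c(3, 3, nf)), atoms = top$atoms)
}

#' Resolve atom indices by residue name and atom name
#'
#' Convenience selector for site sets, e.g. all threonine hydroxyl oxygens:
#' `select_atoms(traj, resname = "THR", name = "OG1")`.
#'
#' @param traj a `wtraj` object.
#' @param resname,name,resid optional filters; `NULL` means no constraint.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(traj, resname = NULL, name = NULL, resid = NULL) {
  keep <- rep(TRUE, nrow(traj$atoms))
  if (!is.null(resname)) keep <- keep & traj$atoms$resname %in% resname
  if (!is.null(name)) keep <- keep & traj$atoms$name %in% name
  if (!is.null(resid)) keep <- keep & traj$atoms$resid %in% resid
  which(keep)
}
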