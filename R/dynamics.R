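## Water mobility and shell-exchange kinetics.
##
## Residence times follow the stable-state picture: a water is in the
## reactant state when H-bonded to an IBS hydroxyl (3.5 A / 35 deg) at a
## time origin, and has reacted once it first moves beyond the product
## cutoff (5.3 A) from the IBS.  The survival correlation
## C(t) = 1 - <p_R(0) p_P(t)> is averaged over origins and members, with
## p_P a first-passage (absorbing) indicator so transient recrossings do
## not terminate a residence.  C(t) is fitted with
## C1 exp(-t/tau1) + C2 exp(-t/tau2) and the mean residence time is the
## amplitude-weighted mean tau = (C1 tau1 + C2 tau2) / (C1 + C2).

#' Unwrap periodic coordinates
#'
#' Reconstructs continuous per-atom paths from wrapped coordinates by
#' accumulating minimum-image steps between consecutive frames. Valid when
#' no atom moves more than half a box length per frame.
#'
#' @param traj a `wtraj` object.
#' @return array like `traj$coords` with unwrapped coordinates.
#' @export
unwrap_trajectory <- function(traj) {
  out <- traj$coords
  nf <- n_frames(traj)
  if (nf < 2L) return(out)
  for (f in 2:nf) {
    step <- min_image(traj$coords[, , f] - traj$coords[, , f - 1L],
                      traj$box[, , f])
    out[, , f] <- out[, , f - 1L] + step
  }
  out
}

#' Mean square displacement with multiple time origins
#'
#' @param traj a `wtraj` object, or an `n_frames x 3 x n_particles` array of
#'   already-unwrapped positions.
#' @param labels water labels to include (ignored for array input; default
#'   all waters).
#' @param max_lag maximum lag in frames (must be below the frame count).
#' @param unwrap unwrap wrapped coordinates first (default TRUE; trajectory
#'   input only).
#' @param pmap optional `perm_map`: compute the MSD of permuted-label series.
#' @return data.frame with columns `lag` (frames), `t` (ps), `msd`
#'   (Angstrom^2), `n_origins`.
#' @export
msd <- function(traj, labels = NULL, max_lag, unwrap = TRUE, pmap = NULL) {
  if (inherits(traj, "wtraj")) {
    if (is.null(labels)) labels <- seq_len(n_waters(traj))
    if (is.null(pmap) && unwrap) {
      un <- unwrap_trajectory(traj)
      nf <- n_frames(traj)
      pos <- array(NA_real_, c(nf, 3, length(labels)))
      for (j in seq_along(labels))
        pos[, , j] <- t(un[traj$waters$O[labels[j]], , ])
    } else {
      nf <- n_frames(traj)
      pos <- array(NA_real_, c(nf, 3, length(labels)))
      for (j in seq_along(labels))
        pos[, , j] <- permuted_coords(traj, pmap, labels[j], "O")
    }
    dt <- traj$dt
  } else {
    pos <- traj
    nf <- dim(pos)[1]
    dt <- attr(pos, "dt") %||% 1
  }
  if (max_lag >= nf) stop("max_lag must be below the trajectory length")
  lags <- seq_len(max_lag)
  out <- vapply(lags, function(L) {
    d <- pos[(1 + L):nf, , , drop = FALSE] - pos[1:(nf - L), , , drop = FALSE]
    s2 <- d[, 1, ]^2 + d[, 2, ]^2 + d[, 3, ]^2
    c(mean(s2), nf - L)
  }, numeric(2))
  data.frame(lag = lags, t = lags * dt, msd = out[1, ], n_origins = out[2, ])
}

#' Diffusion coefficient from an MSD curve (Einstein relation)
#'
#' Fits `MSD(t) = 6 D t` by least squares over the chosen lag window.
#'
#' @param msd_table output of [msd()].
#' @param fit_range optional `c(t_min, t_max)` in ps; default: all lags.
#' @return D in Angstrom^2/ps.
#' @export
msd_diffusion <- function(msd_table, fit_range = NULL) {
  tb <- msd_table
  if (!is.null(fit_range)) tb <- tb[tb$t >= fit_range[1] & tb$t <= fit_range[2], ]
  unname(coef(stats::lm(msd ~ 0 + t, tb))[1] / 6)
}

#' Stable-state-picture state definition
#'
#' @param reactant_criterion [hbond_criterion()] defining the bound state
#'   (default 3.5 A / 35 deg).
#' @param product_distance distance from the IBS beyond which a water has
#'   reacted, Angstrom (default 5.3, i.e. 0.53 nm, chosen from the
#'   site-water RDF's first solvation minimum).
#' @return list of class `ssp_state_def`.
#' @export
ssp_state_definition <- function(reactant_criterion = hbond_criterion(3.5, 35),
                                 product_distance = 5.3) {
  if (product_distance <= reactant_criterion$r_cut)
    stop("product distance must exceed the reactant distance cutoff")
  structure(list(reactant_criterion = reactant_criterion,
                 product_distance = product_distance),
            class = "ssp_state_def")
}

#' Survival correlation from state matrices
#'
#' Core first-passage survival: for every origin where a water is in the
#' reactant state, it contributes 1 at lag t until the first later frame at
#' which it is in the product state, 0 from then on. `C(t)` is the average
#' over all (origin, water) members; `C(0) = 1` and the curve is
#' non-increasing. An instantaneous (non-absorbing) mode is available for
#' comparison.
#'
#' @param reactant logical `n_frames x n_waters` matrix: in reactant state.
#' @param product logical `n_frames x n_waters` matrix: in product region.
#' @param max_lag maximum lag in frames.
#' @param dt frame spacing in ps.
#' @param origin_stride use every `origin_stride`-th frame as an origin
#'   (default 1).
#' @param mode `"first_passage"` (default) or `"instantaneous"`.
#' @return data.frame of class `survival_curve`: `lag`, `t`, `C`,
#'   `n_members`.
#' @export
survival_curve <- function(reactant, product, max_lag, dt = 0.1,
                           origin_stride = 1L,
                           mode = c("first_passage", "instantaneous")) {
  mode <- match.arg(mode)
  nf <- nrow(reactant)
  stopifnot(nrow(product) == nf, ncol(product) == ncol(reactant))
  if (max_lag >= nf) stop("max_lag must be below the trajectory length")
  ## only origins with full lag coverage contribute, so every member spans
  ## every lag and the first-passage average is guaranteed non-increasing
  origins <- seq(1L, nf - max_lag, by = origin_stride)
  surv <- numeric(max_lag + 1L)
  members <- numeric(max_lag + 1L)
  ## first product frame at or after each frame, per water (Inf if never)
  nw <- ncol(reactant)
  first_p <- matrix(Inf, nf, nw)
  rows <- seq_len(nf)
  for (w in seq_len(nw)) {
    pos <- ifelse(product[, w], rows, Inf)
    first_p[, w] <- rev(cummin(rev(pos)))
  }
  lags <- 0:max_lag
  for (t0 in origins) {
    mem <- which(reactant[t0, ])
    if (!length(mem)) next
    if (mode == "first_passage") {
      ## first product frame strictly after t0; a member is alive at lag l
      ## while t0 + l < its first passage frame
      fps <- if (t0 + 1L <= nf) first_p[t0 + 1L, mem] else rep(Inf, length(mem))
      sorted <- sort(fps[is.finite(fps)])
      alive <- length(mem) - findInterval(t0 + lags, sorted)
    } else {
      alive <- length(mem) -
        .rowSums(product[t0 + lags, mem, drop = FALSE], max_lag + 1L, length(mem))
    }
    surv <- surv + alive
    members <- members + length(mem)
  }
  if (all(members == 0)) stop("no reactant members at any origin")
  keep <- members > 0
  out <- data.frame(lag = (0:max_lag)[keep], t = (0:max_lag)[keep] * dt,
                    C = surv[keep] / members[keep], n_members = members[keep])
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Stable-state-picture survival correlation from a trajectory
#'
#' Builds the reactant state (H-bonded to a hydroxyl under the reactant
#' criterion) and product state (beyond the product cutoff from all IBS
#' sites) per frame and water, then evaluates [survival_curve()].
#'
#' @param traj a `wtraj` object.
#' @param hydroxyls list with `O`, `H` hydroxyl atom indices (reactant
#'   anchors, e.g. three mid-ladder threonines).
#' @param ibs_sites atom indices defining the IBS for the product distance
#'   (default: the hydroxyl oxygens).
#' @param state_def an [ssp_state_definition()].
#' @param max_lag maximum lag in frames.
#' @param origin_stride origin spacing in frames (default 1).
#' @param mode passed to [survival_curve()].
#' @return a `survival_curve` data.frame.
#' @export
ssp_survival <- function(traj, hydroxyls, ibs_sites = hydroxyls$O,
                         state_def = ssp_state_definition(),
                         max_lag = n_frames(traj) - 1L, origin_stride = 1L,
                         mode = "first_passage") {
  nf <- n_frames(traj)
  nw <- n_waters(traj)
  reactant <- matrix(FALSE, nf, nw)
  product <- matrix(FALSE, nf, nw)
  w <- traj$waters
  hyd_donors <- data.frame(O = hydroxyls$O, H = hydroxyls$H)
  crit <- state_def$reactant_criterion
  for (f in seq_len(nf)) {
    donated <- detect_hbonds(traj, f, water_donors(traj), hydroxyls$O, crit)
    accepted <- detect_hbonds(traj, f, hyd_donors, w$O, crit)
    bonded_o <- unique(c(donated$donor_o, accepted$acceptor_o))
    reactant[f, ] <- w$O %in% bonded_o
    box <- traj$box[, , f]
    ow <- matrix(traj$coords[w$O, , f], ncol = 3)
    ## all site-water displacements in one minimum-image pass
    ns <- length(ibs_sites)
    sites_m <- matrix(traj$coords[ibs_sites, , f], ncol = 3)
    dmat <- ow[rep(seq_len(nw), each = ns), , drop = FALSE] -
      sites_m[rep(seq_len(ns), nw), , drop = FALSE]
    dd <- sqrt(rowSums(min_image(dmat, box)^2))
    dmin <- apply(matrix(dd, ns, nw), 2, min)
    product[f, ] <- dmin > state_def$product_distance
  }
  survival_curve(reactant, product, max_lag = max_lag, dt = traj$dt,
                 origin_stride = origin_stride, mode = mode)
}

#' Fit a bi-exponential decay to a survival curve
#'
#' Least-squares fit of `C(t) = C1 exp(-t/tau1) + C2 exp(-t/tau2)` with
#' non-negative amplitudes and positive timescales, initialized from a
#' two-segment log-linear split and refined with Levenberg-Marquardt.
#' Points below `c_min` are discarded before fitting. Timescales are
#' reported with `tau1 <= tau2`; the mean residence time is
#' `tau = (C1 tau1 + C2 tau2) / (C1 + C2)`. Two robustness rules apply:
#' timescales are bounded above by five observation windows (slower modes
#' are not identifiable from the data), and a component carrying less than
#' 2% of the total amplitude is treated as a noise-floor artifact and
#' dropped from the mean.
#'
#' @param t lag times in ps (or a `survival_curve` as the single argument).
#' @param C survival values.
#' @param c_min smallest `C` value kept in the fit (default 0.01).
#' @return list of class `kinetics_fit`: `C1`, `tau1`, `C2`, `tau2`, `tau`,
#'   `residual` (RMS), `converged`.
#' @export
fit_biexponential <- function(t, C = NULL, c_min = 0.01) {
  if (is.null(C)) { C <- t$C; t <- t$t }
  keep <- is.finite(C) & C >= c_min
  t <- t[keep]; C <- C[keep]
  if (length(t) < 10L) stop("need at least 10 lag points")
  if (diff(range(C)) < 1e-12) stop("no decay: survival curve is constant")
  ## exponential-peeling initialization: log-linear fit of the tail gives the
  ## slow mode; its subtraction exposes the fast mode at early times
  n <- length(t)
  late <- max(1L, floor(0.6 * n)):n
  lf <- stats::lm(log(pmax(C[late], 1e-12)) ~ t[late])
  tau2_0 <- -1 / coef(lf)[2]
  if (!is.finite(tau2_0) || tau2_0 <= 0) tau2_0 <- diff(range(t))
  C2_0 <- min(C[1], exp(coef(lf)[1]))
  fast <- C - C2_0 * exp(-t / tau2_0)
  early <- which(fast > 0.05 * C[1])
  if (length(early) >= 3L) {
    ef <- stats::lm(log(fast[early]) ~ t[early])
    tau1_0 <- -1 / coef(ef)[2]
    C1_0 <- min(C[1], exp(coef(ef)[1]))
  } else {
    tau1_0 <- tau2_0 / 10
    C1_0 <- 0.5 * C[1]
  }
  if (!is.finite(tau1_0) || tau1_0 <= 0 || tau1_0 >= tau2_0) tau1_0 <- tau2_0 / 10
  if (!is.finite(C1_0) || C1_0 <= 0) C1_0 <- 0.5 * C[1]
  df <- data.frame(t = t, C = C)
  ## timescales beyond a few observation windows are not identifiable from
  ## the data and are excluded by bound
  tau_max <- 5 * diff(range(t))
  tau2_0 <- min(tau2_0, tau_max / 2)
  run_fit <- function(start) tryCatch(
    minpack.lm::nlsLM(C ~ C1 * exp(-t / tau1) + C2 * exp(-t / tau2),
                      data = df, start = start,
                      lower = c(0, 1e-9, 0, 1e-9),
                      upper = c(Inf, tau_max, Inf, tau_max),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  fit <- run_fit(list(C1 = C1_0, tau1 = tau1_0, C2 = C2_0, tau2 = tau2_0))
  if (is.null(fit))
    fit <- run_fit(list(C1 = 0.5 * C[1], tau1 = diff(range(t)) / 20,
                        C2 = 0.5 * C[1], tau2 = diff(range(t))))
  if (is.null(fit)) {
    ## the bi-exponential collapses (one amplitude pinned at zero leaves a
    ## singular gradient): the data prefer a single mode, so fit one
    sfit <- tryCatch(
      minpack.lm::nlsLM(C ~ C1 * exp(-t / tau1), data = df,
                        start = list(C1 = C[1], tau1 = tau2_0),
                        lower = c(0, 1e-9), upper = c(Inf, tau_max),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(sfit)) {
      p <- as.list(coef(sfit))
      res <- list(C1 = p$C1, tau1 = p$tau1, C2 = 0, tau2 = p$tau1,
                  tau = p$tau1,
                  residual = sqrt(mean(stats::resid(sfit)^2)),
                  converged = TRUE)
      class(res) <- "kinetics_fit"
      return(res)
    }
    ## last resort: log-linear, reported as non-converged
    lf <- stats::lm(log(pmax(C, 1e-12)) ~ t)
    tau <- -1 / coef(lf)[2]
    res <- list(C1 = unname(exp(coef(lf)[1])), tau1 = unname(tau), C2 = 0,
                tau2 = unname(tau), tau = unname(tau), residual = NA_real_,
                converged = FALSE)
    class(res) <- "kinetics_fit"
    return(res)
  }
  p <- as.list(coef(fit))
  if (p$tau1 > p$tau2) p <- list(C1 = p$C2, tau1 = p$tau2, C2 = p$C1, tau2 = p$tau1)
  denom <- p$C1 + p$C2
  if (denom <= 0) stop("degenerate fit: both amplitudes zero")
  ## a component carrying < 2% of the amplitude is a noise-floor artifact,
  ## not an interpretable relaxation mode; drop it from the mean
  w <- c(p$C1, p$C2) / denom
  w[w < 0.02] <- 0
  res <- list(C1 = p$C1, tau1 = p$tau1, C2 = p$C2, tau2 = p$tau2,
              tau = sum(w * c(p$tau1, p$tau2)) / sum(w),
              residual = sqrt(mean(stats::resid(fit)^2)), converged = TRUE)
  class(res) <- "kinetics_fit"
  res
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> C(t) = %.3f exp(-t/%.2f ps) + %.3f exp(-t/%.2f ps)\n",
              x$C1, x$tau1, x$C2, x$tau2))
  cat(sprintf("  mean residence time tau = %.2f ps (RMS residual %.2g)\n",
              x$tau, x$residual))
  invisible(x)
}

#' Mean residence time of a kinetics fit
#'
#' @param fit a `kinetics_fit`.
#' @return tau in ps.
#' @export
residence_time <- function(fit) fit$tau
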