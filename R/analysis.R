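#' Radius of gyration and principal-axis components
#'
#' `Rg` is the root-mean-square bead distance from the (unit-mass) center
#' of mass.  Components are the square roots of the gyration tensor's
#' eigenvalues, sorted ascending so that `Rgz` lies along the chain's long
#' axis; the identity `Rg^2 = Rgx^2 + Rgy^2 + Rgz^2` holds exactly (it is
#' the tensor trace).
#'
#' @param frame an `hnp_state` or an N x 3 coordinate matrix (nm).
#' @return list of class `hnp_gyration` with `Rg`, `Rgx`, `Rgy`, `Rgz`
#'   (nm) and `axes` (3 x 3 matrix, eigenvectors in columns; the last
#'   column is the long axis).
#' @export
gyration <- function(frame) {
  pos <- if (inherits(frame, "hnp_state")) frame$positions else as.matrix(frame)
  n <- nrow(pos)
  rc <- colMeans(pos)
  d <- sweep(pos, 2, rc)
  S <- crossprod(d) / n                 # gyration tensor
  ev <- eigen(S, symmetric = TRUE)
  lam <- rev(ev$values)                 # ascending
  lam[lam < 0] <- 0                     # guard tiny negative round-off
  axes <- ev$vectors[, 3:1, drop = FALSE]
  structure(list(Rg = sqrt(sum(lam)), Rgx = sqrt(lam[1]), Rgy = sqrt(lam[2]),
                 Rgz = sqrt(lam[3]), axes = axes),
            class = "hnp_gyration")
}

#' @export
print.hnp_gyration <- function(x, ...) {
  cat(sprintf("<hnp_gyration> Rg=%.4g nm (x=%.4g, y=%.4g, z=%.4g)\n",
              x$Rg, x$Rgx, x$Rgy, x$Rgz))
  invisible(x)
}

#' Global bond orientational order parameter
#'
#' The second-Legendre average `P = <(3 cos^2 a - 1)/2>` over bond vectors,
#' where `a` is the angle between each bond and the chain's long axis (the
#' gyration-tensor eigenvector with the largest eigenvalue).  `P` is 1 for
#' perfectly parallel bonds, ~0 for an isotropic coil and -0.5 for bonds
#' perpendicular to the axis.
#'
#' @param frame an `hnp_state` or N x 3 coordinate matrix.
#' @param axis optional explicit reference axis (3-vector); default is the
#'   principal gyration axis.
#' @param all_bonds average over all N-1 bonds (default); `FALSE`
#'   reproduces the literal N-2 bond form (bonds 2..N-1 of the formula),
#'   identical in the parallel/random limits.
#' @return scalar in [-0.5, 1].
#' @export
orientational_order <- function(frame, axis = NULL, all_bonds = TRUE) {
  pos <- if (inherits(frame, "hnp_state")) frame$positions else as.matrix(frame)
  n <- nrow(pos)
  if (n < 3) stop("need at least 3 beads")
  if (is.null(axis)) axis <- gyration(pos)$axes[, 3]
  axis <- axis / sqrt(sum(axis^2))
  b <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
  if (!all_bonds) b <- b[-1, , drop = FALSE]
  bn <- sqrt(rowSums(b^2))
  ok <- bn > 1e-12
  if (!all(ok)) warning(sum(!ok), " zero-length bond(s) skipped")
  ca <- (b[ok, , drop = FALSE] %*% axis) / bn[ok]
  mean((3 * ca^2 - 1) / 2)
}

#' Dihedral angles of a chain, measured from the trans state
#'
#' Returns the N-3 dihedral angles in (-pi, pi] with phi = 0 at trans
#' (extended zigzag), matching the torsion term's convention.  Degenerate
#' (collinear) quadruplets are assigned phi = 0.
#'
#' @param frame an `hnp_state` or N x 3 coordinate matrix.
#' @return numeric vector of length N-3 (radians).
#' @export
dihedral_angles <- function(frame) {
  pos <- if (inherits(frame, "hnp_state")) frame$positions else as.matrix(frame)
  n <- nrow(pos)
  if (n < 4) stop("need at least 4 beads")
  b <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]   # n-1 bonds
  b1 <- b[1:(n - 3), , drop = FALSE]
  b2 <- b[2:(n - 2), , drop = FALSE]
  b3 <- b[3:(n - 1), , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cr(n1, n2) * b2) / b2n
  phi_std <- atan2(y, x)                       # cis = 0
  phi <- ifelse(phi_std > 0, phi_std - pi, phi_std + pi)  # trans = 0
  degen <- rowSums(n1^2) < 1e-18 | rowSums(n2^2) < 1e-18
  phi[degen] <- 0
  if (any(degen)) attr(phi, "n_degenerate") <- sum(degen)
  phi
}

#' Classify dihedrals as trans or gauche
#'
#' A dihedral is trans when `|phi| <= pi/3` (phi measured from the trans
#' state), gauche otherwise.
#'
#' @param frame an `hnp_state` or N x 3 coordinate matrix.
#' @return character vector of length N-3 over {"trans", "gauche"}.
#' @export
dihedral_states <- function(frame) {
  phi <- dihedral_angles(frame)
  out <- ifelse(abs(phi) <= pi / 3, "trans", "gauche")
  ndeg <- attr(phi, "n_degenerate")
  if (!is.null(ndeg)) warning(ndeg, " degenerate dihedral(s) labeled trans")
  out
}

#' Stem lengths from a trans/gauche label sequence
#'
#' A stem is a maximal run of more than `min_stem - 1` consecutive
#' all-trans bonds; by default runs of at least 4 ("more than three").
#' Stem lengths are counted in dihedral units: an all-trans chain of N
#' beads yields a single stem of length N-3.
#'
#' @param labels character vector over {"trans", "gauche"} (e.g. from
#'   [dihedral_states()]).
#' @param min_stem minimum run length counting as a stem (default 4).
#' @return integer vector of stem lengths (possibly empty).
#' @export
stems <- function(labels, min_stem = 4L) {
  stopifnot(length(labels) >= 1, all(labels %in% c("trans", "gauche")))
  r <- rle(labels)
  lens <- r$lengths[r$values == "trans"]
  as.integer(lens[lens >= min_stem])
}

#' Stem-length distribution pooled over trajectory frames
#'
#' @param frames a list of `hnp_state`s/coordinate matrices, an
#'   `hnp_trajectory` (production frames only; see [production_frames()]),
#'   or a single frame.
#' @param min_stem minimum stem length (default 4).
#' @param equilibration_fraction passed to [production_frames()] when
#'   `frames` is a trajectory.
#' @param leg optional leg restriction for trajectories.
#' @return object of class `hnp_stem_distribution`: data.frame with columns
#'   `Ntr` and `probability` (summing to 1), plus attribute
#'   `n_stems_observed`.
#' @export
stem_distribution <- function(frames, min_stem = 4L,
                              equilibration_fraction = 0.5, leg = NULL) {
  if (inherits(frames, "hnp_trajectory")) {
    idx <- production_frames(frames, equilibration_fraction, leg)
    frames <- lapply(idx, function(i) trajectory_frame(frames, i))
  }
  if (inherits(frames, "hnp_state") || is.matrix(frames)) frames <- list(frames)
  all_stems <- unlist(lapply(frames, function(f)
    stems(suppressWarnings(dihedral_states(f)), min_stem)))
  if (length(all_stems) == 0) {
    out <- data.frame(Ntr = integer(0), probability = numeric(0))
  } else {
    tab <- table(all_stems)
    out <- data.frame(Ntr = as.integer(names(tab)),
                      probability = as.numeric(tab) / sum(tab))
  }
  attr(out, "n_stems_observed") <- length(all_stems)
  class(out) <- c("hnp_stem_distribution", "data.frame")
  out
}

#' Long-range residue contact count
#'
#' Counts unordered bead pairs within `Rcut` in space but more than `lcut`
#' residues apart in sequence — a proxy for tertiary interactions.
#'
#' @param frame an `hnp_state` or N x 3 coordinate matrix.
#' @param Rcut contact distance cutoff in nm (default 0.65).
#' @param lcut sequence-separation cutoff; pairs with `|i - j| > lcut`
#'   qualify (default 3, i.e. separation >= 4, matching the nonbonded
#'   exclusion).
#' @return nonnegative integer.
#' @export
contact_count <- function(frame, Rcut = 0.65, lcut = 3L) {
  pos <- if (inherits(frame, "hnp_state")) frame$positions else as.matrix(frame)
  stopifnot(Rcut > 0, lcut >= 0)
  cpp_contact_count(pos, Rcut, as.integer(lcut))
}

#' Contact pair list of a frame
#'
#' @inheritParams contact_count
#' @return data.frame with columns `i`, `j` (1-based, i < j) and
#'   `distance` (nm).
#' @export
contact_pairs <- function(frame, Rcut = 0.65, lcut = 3L) {
  pos <- if (inherits(frame, "hnp_state")) frame$positions else as.matrix(frame)
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(d) & d <= Rcut &
                 abs(row(d) - col(d)) > lcut, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             distance = d[idx])[order(idx[, 1], idx[, 2]), ]
}

#' Ensemble summary of a temperature leg
#'
#' Time-averages every observable over the production frames of one
#' trajectory leg: per-bond energies (from the sampled time series),
#' gyration radius and components, orientational order, contact count.
#' Bootstrap standard errors (resampling frames) accompany the frame-based
#' observables.
#'
#' @param traj an `hnp_trajectory`.
#' @param leg leg number (default: every leg, one row each).
#' @param equilibration_fraction fraction of each leg discarded (default 0.5).
#' @param n_boot bootstrap resamples (default 200).
#' @param boot_seed seed for the bootstrap resampling.
#' @param contact_spec list with `Rcut`, `lcut` (defaults 0.65 nm, 3).
#' @return data.frame, one row per leg: `Tstar`, `leg`, `n_frames`,
#'   per-bond mean energies, `Rg`, `Rgx`, `Rgy`, `Rgz`, `P`, `contacts`,
#'   and `*_se` bootstrap errors.
#' @export
sweep_summary <- function(traj, leg = NULL, equilibration_fraction = 0.5,
                          n_boot = 200L, boot_seed = 1L,
                          contact_spec = list(Rcut = 0.65, lcut = 3L)) {
  stopifnot(inherits(traj, "hnp_trajectory"))
  legs <- if (is.null(leg)) unique(traj$frame_info$leg) else leg
  n <- dim(traj$frames)[2]
  rows <- lapply(legs, function(l) {
    idx <- production_frames(traj, equilibration_fraction, l)
    if (length(idx) == 0) {
      warning("leg ", l, " has no production frames; omitted")
      return(NULL)
    }
    sm <- traj$samples
    legsm <- sm[sm$leg == l, , drop = FALSE]
    cut <- min(legsm$step) + equilibration_fraction *
      (max(legsm$step) - min(legsm$step))
    legsm <- legsm[legsm$step > cut, , drop = FALSE]
    per_frame <- vapply(idx, function(i) {
      fr <- trajectory_frame(traj, i)
      g <- gyration(fr)
      c(Rg = g$Rg, Rgx = g$Rgx, Rgy = g$Rgy, Rgz = g$Rgz,
        P = orientational_order(fr),
        contacts = contact_count(fr, contact_spec$Rcut, contact_spec$lcut))
    }, numeric(6))
    means <- rowMeans(per_frame)
    set.seed(as.integer(boot_seed) + l)
    boot <- replicate(n_boot, {
      j <- sample(ncol(per_frame), replace = TRUE)
      rowMeans(per_frame[, j, drop = FALSE])
    })
    ses <- apply(boot, 1, sd)
    data.frame(
      Tstar = traj$frame_info$Tstar_target[idx[1]], leg = l,
      n_frames = length(idx),
      per_bond_stretch_bend = mean(legsm$stretch + legsm$bend) / (n - 1),
      per_bond_stretch = mean(legsm$stretch) / (n - 1),
      per_angle_bend = mean(legsm$bend) / (n - 2),
      per_dihedral_torsion = mean(legsm$torsion) / (n - 3),
      per_bond_torsion = mean(legsm$torsion) / (n - 1),
      per_bond_nonbonded = mean(legsm$nonbonded) / (n - 1),
      per_bond_total = mean(legsm$potential) / (n - 1),
      Rg = means["Rg"], Rgx = means["Rgx"], Rgy = means["Rgy"],
      Rgz = means["Rgz"], P = means["P"], contacts = means["contacts"],
      Rg_se = ses[1], P_se = ses[5], contacts_se = ses[6],
      row.names = NULL)
  })
  do.call(rbind, rows)
}
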