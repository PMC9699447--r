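#' Construct the coarse-grained HNP force field
#'
#' Four terms act on a chain of C-alpha beads:
#' \itemize{
#'   \item stretch: `sum_i 1/2 kd (l_i - l0)^2` over the N-1 bonds;
#'   \item bend: `sum_i 1/2 ktheta (theta_i - theta0)^2` over the N-2 bond
#'     angles, with `theta` the deflection angle between consecutive bond
#'     vectors (0 for a straight chain; `theta0` = 1.231 rad is the
#'     tetrahedral supplement, valence angle 109.5 degrees);
#'   \item torsion: `sum_i 1/2 kphi (1 - cos 3 phi_i)` over the N-3
#'     dihedrals, with `phi` measured from the trans state (phi = 0 is
#'     trans), giving minima at trans and gauche+/- and a barrier of `kphi`;
#'   \item nonbonded: truncated 12-6 Lennard-Jones
#'     `4 eps(a,b) [(sigma/r)^12 - Lambda(a,b) (sigma/r)^6]` between beads at
#'     least 4 residues apart, cut at `Rc` (and by default shifted so the
#'     potential is continuous at the cutoff).
#' }
#' The pair matrices make H-H the only attractive pair (`Lambda` = 1) and
#' P-P doubly repulsive (`Lambda` = -1); all other pairs are soft repulsive
#' (`Lambda` = 0) with reduced strengths.
#'
#' @param l0 equilibrium bond length, nm.
#' @param kd stretch constant, kcal/(nm^2 mol).
#' @param theta0 equilibrium bond angle, rad.
#' @param ktheta bend constant, kcal/(rad^2 mol).
#' @param kphi torsion constant (barrier height), kcal/mol.
#' @param sigma Lennard-Jones length, nm.
#' @param eps_h base Lennard-Jones energy (H-H well depth), kcal/mol.
#' @param Rc nonbonded cutoff, nm.
#' @param epsilon_matrix,lambda_matrix optional 3x3 symmetric overrides
#'   (rows/columns ordered H, N, P).
#' @param shift_at_cutoff logical; shift each pair potential to zero at `Rc`
#'   (keeps the energy continuous; forces are unaffected).
#' @return object of class `hnp_forcefield` (a named list).
#' @examples
#' ff <- forcefield()
#' ff$epsilon_matrix
#' @export
forcefield <- function(l0 = 0.153, kd = 7e4, theta0 = 1.231, ktheta = 100,
                       kphi = 2.0, sigma = 0.3624, eps_h = 0.1984, Rc = 0.95,
                       epsilon_matrix = NULL, lambda_matrix = NULL,
                       shift_at_cutoff = TRUE) {
  if (is.null(epsilon_matrix)) {
    epsilon_matrix <- eps_h * matrix(c(
      1,      2 / 3,  7 / 12,
      2 / 3,  1 / 3,  1 / 4,
      7 / 12, 1 / 4,  1 / 6), 3, 3, byrow = TRUE)
  }
  if (is.null(lambda_matrix)) {
    lambda_matrix <- matrix(c(
      1, 0, 0,
      0, 0, 0,
      0, 0, -1), 3, 3, byrow = TRUE)
  }
  dimnames(epsilon_matrix) <- dimnames(lambda_matrix) <-
    list(residue_classes, residue_classes)
  stopifnot(isSymmetric(unname(epsilon_matrix)),
            isSymmetric(unname(lambda_matrix)),
            all(epsilon_matrix > 0), l0 > 0, kd > 0, ktheta > 0,
            sigma > 0, Rc > sigma)
  structure(
    list(l0 = l0, kd = kd, theta0 = theta0, ktheta = ktheta, kphi = kphi,
         sigma = sigma, eps_h = eps_h, Rc = Rc,
         epsilon_matrix = epsilon_matrix, lambda_matrix = lambda_matrix,
         shift_at_cutoff = shift_at_cutoff),
    class = "hnp_forcefield")
}

#' @export
print.hnp_forcefield <- function(x, ...) {
  cat("<hnp_forcefield> l0=", x$l0, " nm, kd=", x$kd,
      ", theta0=", x$theta0, " rad, ktheta=", x$ktheta,
      ", kphi=", x$kphi, ", sigma=", x$sigma, " nm, eps_h=", x$eps_h,
      ", Rc=", x$Rc, " nm, shifted=", x$shift_at_cutoff, "\n", sep = "")
  invisible(x)
}

#' Read or write force-field parameters as JSON
#'
#' @param ff an `hnp_forcefield`.
#' @param path file path.
#' @return `read_forcefield` returns an `hnp_forcefield`; `write_forcefield`
#'   returns `path` invisibly.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "hnp_forcefield"))
  jsonlite::write_json(unclass(ff), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  forcefield(l0 = x$l0, kd = x$kd, theta0 = x$theta0, ktheta = x$ktheta,
             kphi = x$kphi, sigma = x$sigma, eps_h = x$eps_h, Rc = x$Rc,
             epsilon_matrix = matrix(unlist(x$epsilon_matrix), 3, 3),
             lambda_matrix = matrix(unlist(x$lambda_matrix), 3, 3),
             shift_at_cutoff = isTRUE(x$shift_at_cutoff))
}

#' Nonbonded pair potential between two residue classes
#'
#' Truncated (optionally shifted) 12-6 Lennard-Jones for one bead pair.
#' Vectorized over `r`.
#'
#' @param a,b residue class labels ("H", "N" or "P").
#' @param r interbead distance(s), nm; must be positive.
#' @param ff force field.
#' @param shifted override the force field's `shift_at_cutoff`; set
#'   `FALSE` for the unshifted (raw) potential.
#' @return energy in kcal/mol (0 beyond the cutoff).
#' @examples
#' pair_potential("H", "H", 0.3624)   # zero crossing at r = sigma
#' @export
pair_potential <- function(a, b, r, ff = forcefield(),
                           shifted = ff$shift_at_cutoff) {
  if (any(r <= 0)) stop("pair distance must be positive")
  eps <- ff$epsilon_matrix[a, b]
  lam <- ff$lambda_matrix[a, b]
  s6 <- (ff$sigma / r)^6
  u <- 4 * eps * (s6^2 - lam * s6)
  if (shifted) {
    s6c <- (ff$sigma / ff$Rc)^6
    u <- u - 4 * eps * (s6c^2 - lam * s6c)
  }
  ifelse(r > ff$Rc, 0, u)
}

.ff_for_cpp <- function(ff) {
  ff$epsilon_matrix <- unname(ff$epsilon_matrix)
  ff$lambda_matrix <- unname(ff$lambda_matrix)
  unclass(ff)
}

#' Potential energy terms of a chain state
#'
#' `stretch_energy`, `bend_energy`, `torsion_energy` and `nonbonded_energy`
#' return single terms; [energy_breakdown()] returns all of them with
#' per-bond normalizations and [total_energy_and_forces()] adds analytic
#' forces.
#'
#' @param state an `hnp_state`.
#' @param ff force field.
#' @return energy in kcal/mol.
#' @export
stretch_energy <- function(state, ff = forcefield()) {
  .validate_state(state)
  cpp_energy_forces(state$positions, .class_index(state$sequence),
                    .ff_for_cpp(ff))$stretch
}

#' @rdname stretch_energy
#' @export
bend_energy <- function(state, ff = forcefield()) {
  .validate_state(state)
  cpp_energy_forces(state$positions, .class_index(state$sequence),
                    .ff_for_cpp(ff))$bend
}

#' @rdname stretch_energy
#' @export
torsion_energy <- function(state, ff = forcefield()) {
  .validate_state(state)
  cpp_energy_forces(state$positions, .class_index(state$sequence),
                    .ff_for_cpp(ff))$torsion
}

#' @rdname stretch_energy
#' @export
nonbonded_energy <- function(state, ff = forcefield()) {
  .validate_state(state)
  cpp_energy_forces(state$positions, .class_index(state$sequence),
                    .ff_for_cpp(ff))$nonbonded
}

#' Full energy breakdown with per-term normalizations
#'
#' Normalizations divide by the natural counting unit of each term: N-1
#' bonds for stretch/bend/nonbonded/total, N-2 angles for bend's own
#' `per_angle`, N-3 dihedrals for torsion's `per_dihedral`.
#'
#' @inheritParams stretch_energy
#' @return object of class `hnp_energy`: list with `stretch`, `bend`,
#'   `torsion`, `nonbonded`, `total` plus normalized variants.
#' @export
energy_breakdown <- function(state, ff = forcefield()) {
  .validate_state(state)
  n <- nrow(state$positions)
  e <- cpp_energy_forces(state$positions, .class_index(state$sequence),
                         .ff_for_cpp(ff))
  structure(list(
    stretch = e$stretch, bend = e$bend, torsion = e$torsion,
    nonbonded = e$nonbonded, total = e$total,
    per_bond_stretch_bend = (e$stretch + e$bend) / (n - 1),
    per_angle = e$bend / (n - 2),
    per_dihedral = e$torsion / (n - 3),
    per_bond_nonbonded = e$nonbonded / (n - 1),
    per_bond_total = e$total / (n - 1)),
    class = "hnp_energy")
}

#' @export
print.hnp_energy <- function(x, ...) {
  cat("<hnp_energy> (kcal/mol)\n")
  for (k in c("stretch", "bend", "torsion", "nonbonded", "total"))
    cat(sprintf("  %-10s %12.6g\n", k, x[[k]]))
  invisible(x)
}

#' Total energy and analytic forces
#'
#' Forces are the exact negative gradients of the four potential terms,
#' in kcal/(mol nm).  They satisfy Newton's third law (net force ~ 0) and,
#' being internal, exert no net torque about the center of mass.
#'
#' @inheritParams stretch_energy
#' @return list with `energy` (an `hnp_energy`) and `forces` (N x 3 matrix).
#' @export
total_energy_and_forces <- function(state, ff = forcefield()) {
  .validate_state(state)
  d <- as.matrix(stats::dist(state$positions))
  diag(d) <- Inf
  if (min(d) < 1e-4)
    stop("singular configuration: bead pair closer than 1e-4 nm")
  e <- energy_breakdown(state, ff)
  f <- cpp_energy_forces(state$positions, .class_index(state$sequence),
                         .ff_for_cpp(ff))$forces
  list(energy = e, forces = f)
}
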