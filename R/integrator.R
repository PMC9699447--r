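#' Remove net translation and rotation from a chain state
#'
#' Subtracts the center-of-mass velocity, then the rigid rotation
#' `omega x r` with `omega = I^-1 L` (inertia tensor about the center of
#' mass).  Both projections leave internal motion minimally perturbed and
#' are idempotent; applying the angular projection does not reintroduce
#' linear momentum.
#'
#' @param state an `hnp_state`.
#' @return the state with net linear and angular momentum below ~1e-10
#'   in simulation units (g/mol nm/ps).
#' @export
remove_rigid_motion <- function(state) {
  .validate_state(state)
  m <- state$masses
  M <- sum(m)
  vcom <- colSums(state$velocities * m) / M
  v <- sweep(state$velocities, 2, vcom)
  com <- colSums(state$positions * m) / M
  rr <- sweep(state$positions, 2, com)
  # angular momentum and inertia tensor about the COM
  L <- colSums(m * cbind(
    rr[, 2] * v[, 3] - rr[, 3] * v[, 2],
    rr[, 3] * v[, 1] - rr[, 1] * v[, 3],
    rr[, 1] * v[, 2] - rr[, 2] * v[, 1]))
  r2 <- rowSums(rr^2)
  I <- diag(sum(m * r2), 3) - crossprod(rr * sqrt(m), rr * sqrt(m))
  # guard: a perfectly collinear chain has a singular inertia tensor
  omega <- tryCatch(solve(I, L), error = function(e) {
    ev <- eigen(I, symmetric = TRUE)
    keep <- ev$values > 1e-10 * max(ev$values)
    ev$vectors[, keep, drop = FALSE] %*%
      (crossprod(ev$vectors[, keep, drop = FALSE], L) / ev$values[keep])
  })
  v <- v - cbind(
    omega[2] * rr[, 3] - omega[3] * rr[, 2],
    omega[3] * rr[, 1] - omega[1] * rr[, 3],
    omega[1] * rr[, 2] - omega[2] * rr[, 1])
  state$velocities <- v
  state
}

#' Net linear and angular momentum of a state
#'
#' @param state an `hnp_state`.
#' @return list with `linear` and `angular` momentum 3-vectors
#'   (g/mol nm/ps and g/mol nm^2/ps, about the center of mass).
#' @export
net_momenta <- function(state) {
  m <- state$masses
  com <- colSums(state$positions * m) / sum(m)
  rr <- sweep(state$positions, 2, com)
  v <- state$velocities
  list(
    linear = colSums(v * m),
    angular = colSums(m * cbind(
      rr[, 2] * v[, 3] - rr[, 3] * v[, 2],
      rr[, 3] * v[, 1] - rr[, 1] * v[, 3],
      rr[, 1] * v[, 2] - rr[, 2] * v[, 1])))
}

#' Instantaneous kinetic temperature
#'
#' `T_kin = 2 K / (N_free kB)` with `N_free = 3N - 6` (net translation and
#' rotation removed) and `K` the kinetic energy in kcal/mol.
#'
#' @param state an `hnp_state`.
#' @param reduced return the reduced temperature `T* = kB T / eps_h`.
#' @param ff force field (only `eps_h` is used, for `reduced = TRUE`).
#' @return temperature in K, or reduced units if `reduced = TRUE`.
#' @export
kinetic_temperature <- function(state, reduced = FALSE, ff = forcefield()) {
  K <- 0.5 * sum(state$masses * rowSums(state$velocities^2)) / .kcal
  nfree <- 3 * nrow(state$positions) - 6
  Tk <- 2 * K / (nfree * .kB)
  if (reduced) kelvin_to_tstar(Tk, ff) else Tk
}

#' Advance a chain state by velocity-Verlet steps
#'
#' One call performs `n_steps` velocity-Verlet updates.  With
#' `Tstar = NULL` the move is plain (symplectic) NVE; with a target
#' temperature, velocities couple to a single Nose-Hoover thermostat with
#' coupling mass `Q = N_free kB T tau^2`.
#'
#' @param state an `hnp_state`.
#' @param ff force field.
#' @param n_steps number of steps (default 1).
#' @param dt time step in fs (default 2.5).
#' @param Tstar thermostat target as reduced temperature, or `NULL` for NVE.
#' @param tau thermostat relaxation constant in fs (default 25).
#' @param xi initial thermostat friction variable (1/ps); kept across calls
#'   via the returned state's `xi` field.
#' @param frame_stride,sample_stride strides (in steps) for stored frames
#'   and scalar samples; defaults store only start and end.
#' @return an `hnp_state` with updated positions/velocities/time, plus
#'   attributes `samples` (matrix of per-sample energies, kinetic
#'   temperature and xi) and `frames` (n_frames x N x 3 array).
#' @export
step_md <- function(state, ff = forcefield(), n_steps = 1L, dt = 2.5,
                    Tstar = NULL, tau = 25, xi = state$xi,
                    frame_stride = n_steps, sample_stride = n_steps) {
  .validate_state(state)
  stopifnot(dt > 0, n_steps >= 1)
  if (is.null(xi)) xi <- 0
  Tk <- if (is.null(Tstar)) -1 else tstar_to_kelvin(Tstar, ff)
  res <- cpp_run_md(state$positions, state$velocities, state$masses,
                    .class_index(state$sequence), .ff_for_cpp(ff),
                    dt * 1e-3, as.integer(n_steps), Tk, tau * 1e-3,
                    as.integer(frame_stride), as.integer(sample_stride), xi)
  out <- state
  out$positions <- res$positions
  out$velocities <- res$velocities
  out$time <- state$time + n_steps * dt * 1e-3
  out$xi <- res$xi
  attr(out, "samples") <- res$samples
  attr(out, "frames") <- res$frames
  attr(out, "frame_steps") <- res$frame_steps
  out
}

#' Define a run protocol for a quench simulation
#'
#' @param schedule data.frame (or list of pairs) with columns `Tstar` and
#'   `steps`: successive thermostat legs.  The chain is initialized at the
#'   first leg's temperature (high-temperature coil), then each leg runs
#'   with the thermostat retargeted — a quench when the temperature drops.
#' @param dt time step in fs.
#' @param tau thermostat relaxation constant in fs.
#' @param seed integer seed controlling the initial configuration and
#'   velocities (all randomness flows from here).
#' @param snapshot_stride steps between saved frames.
#' @param sample_stride steps between scalar samples (energies, T).
#' @return object of class `hnp_protocol`.
#' @export
run_protocol <- function(schedule, dt = 2.5, tau = 25, seed = 1L,
                         snapshot_stride = 500L, sample_stride = 50L) {
  if (is.list(schedule) && !is.data.frame(schedule))
    schedule <- do.call(rbind, lapply(schedule, function(x)
      data.frame(Tstar = x[[1]], steps = x[[2]])))
  stopifnot(is.data.frame(schedule), all(c("Tstar", "steps") %in% names(schedule)),
            nrow(schedule) >= 1, all(schedule$Tstar > 0), all(schedule$steps >= 1),
            dt > 0, tau > 0)
  structure(list(schedule = schedule, dt = dt, tau = tau,
                 seed = as.integer(seed),
                 snapshot_stride = as.integer(snapshot_stride),
                 sample_stride = as.integer(sample_stride)),
            class = "hnp_protocol")
}

#' Run a quench simulation
#'
#' Initializes a random high-temperature coil via [initial_configuration()]
#' at the first scheduled temperature, removes net momenta, then runs each
#' schedule leg under the Nose-Hoover thermostat.  Identical seeds give
#' bit-identical trajectories.
#'
#' @param seq an `hnp_sequence` (or repeat-unit spec string plus `n`).
#' @param protocol an `hnp_protocol` from [run_protocol()].
#' @param ff force field.
#' @param n chain length, only used when `seq` is a spec string.
#' @return object of class `hnp_trajectory`: list with `frames`
#'   (n_frames x N x 3 array), `frame_info` (data.frame: step, time_ps,
#'   Tstar_target, leg), `samples` (data.frame of scalar time series),
#'   `final_state`, `sequence`, `protocol`, `ff`.
#' @export
run_quench <- function(seq, protocol, ff = forcefield(), n = NULL) {
  if (is.character(seq)) {
    if (is.null(n)) stop("supply chain length `n` with a spec string")
    seq <- build_sequence(seq, n)
  }
  seq <- as_hnp_sequence(seq)
  stopifnot(inherits(protocol, "hnp_protocol"))
  sch <- protocol$schedule
  state <- initial_configuration(seq, seed = protocol$seed,
                                 Tstar = sch$Tstar[1], ff = ff)
  frames <- list(); finfo <- list(); samples <- list()
  t_offset_steps <- 0
  for (leg in seq_len(nrow(sch))) {
    state <- step_md(state, ff, n_steps = sch$steps[leg], dt = protocol$dt,
                     Tstar = sch$Tstar[leg], tau = protocol$tau,
                     frame_stride = protocol$snapshot_stride,
                     sample_stride = protocol$sample_stride)
    fr <- attr(state, "frames")
    fs <- attr(state, "frame_steps")
    sm <- as.data.frame(attr(state, "samples"))
    keep <- if (leg == 1) TRUE else fs > 0   # drop duplicated step-0 frame
    fr <- fr[keep, , , drop = FALSE]
    fs <- fs[keep]
    if (leg > 1) sm <- sm[sm$step > 0, , drop = FALSE]
    frames[[leg]] <- fr
    finfo[[leg]] <- data.frame(
      step = fs + t_offset_steps,
      time_ps = (fs + t_offset_steps) * protocol$dt * 1e-3,
      Tstar_target = sch$Tstar[leg], leg = leg)
    sm$step <- sm$step + t_offset_steps
    sm$Tstar_target <- sch$Tstar[leg]
    sm$leg <- leg
    samples[[leg]] <- sm
    t_offset_steps <- t_offset_steps + sch$steps[leg]
  }
  allframes <- do.call(abind3, frames)
  structure(list(
    frames = allframes,
    frame_info = do.call(rbind, finfo),
    samples = do.call(rbind, samples),
    final_state = state,
    sequence = seq, protocol = protocol, ff = ff),
    class = "hnp_trajectory")
}

# rbind for n x N x 3 arrays along the first axis
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(0, c(sum(vapply(xs, function(x) dim(x)[1], 0)), d[2], d[3]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' @export
print.hnp_trajectory <- function(x, ...) {
  cat("<hnp_trajectory> N=", dim(x$frames)[2], ", ", dim(x$frames)[1],
      " frames, ", nrow(x$protocol$schedule), " leg(s), seed=",
      x$protocol$seed, "\n", sep = "")
  invisible(x)
}

#' Extract one frame of a trajectory as a chain state
#'
#' @param traj an `hnp_trajectory`.
#' @param i frame index (1-based).
#' @return an `hnp_state` (velocities are zero except for the final frame).
#' @export
trajectory_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= dim(traj$frames)[1])
  n <- dim(traj$frames)[2]
  structure(list(
    positions = matrix(traj$frames[i, , ], n, 3),
    velocities = matrix(0, n, 3),
    masses = traj$final_state$masses,
    sequence = traj$sequence,
    time = traj$frame_info$time_ps[i]), class = "hnp_state")
}

#' Indices of production frames of a trajectory
#'
#' The first `equilibration_fraction` of each temperature leg is discarded;
#' the remainder are production frames used for ensemble averages.
#'
#' @param traj an `hnp_trajectory`.
#' @param equilibration_fraction fraction of each leg discarded (default 0.5).
#' @param leg optional leg number(s) to restrict to.
#' @return integer frame indices.
#' @export
production_frames <- function(traj, equilibration_fraction = 0.5, leg = NULL) {
  fi <- traj$frame_info
  legs <- if (is.null(leg)) unique(fi$leg) else leg
  idx <- integer(0)
  for (l in legs) {
    j <- which(fi$leg == l)
    cut <- fi$step[j[1]] + equilibration_fraction *
      (fi$step[j[length(j)]] - fi$step[j[1]])
    idx <- c(idx, j[fi$step[j] > cut])
  }
  idx
}
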