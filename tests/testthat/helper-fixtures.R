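# Shared fixtures and independent oracles, all generated in code.

# Build Cartesian coordinates from internal coordinates: bond lengths,
# deflection angles between consecutive bonds, and dihedrals measured from
# the trans state (phi = 0 is trans).  Independent of the package's own
# geometry code: used as the geometry oracle.
chain_from_internal <- function(n, l = 0.153, theta = 1.231, phi = 0) {
  l <- rep_len(l, n - 1)
  theta <- rep_len(theta, max(n - 2, 1))
  phi <- rep_len(phi, max(n - 3, 1))
  pos <- matrix(0, n, 3)
  pos[2, ] <- c(l[1], 0, 0)
  if (n >= 3) {
    d <- c(cos(theta[1]), sin(theta[1]), 0)
    pos[3, ] <- pos[2, ] + l[2] * d
  }
  if (n >= 4) {
    for (i in 4:n) {
      b2 <- pos[i - 1, ] - pos[i - 2, ]
      b1 <- pos[i - 2, ] - pos[i - 3, ]
      e1 <- b2 / sqrt(sum(b2^2))
      nv <- c(b1[2] * b2[3] - b1[3] * b2[2],
              b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
      nn <- sqrt(sum(nv^2))
      nv <- if (nn < 1e-12) c(0, 0, 1) else nv / nn
      e2 <- c(nv[2] * e1[3] - nv[3] * e1[2],
              nv[3] * e1[1] - nv[1] * e1[3],
              nv[1] * e1[2] - nv[2] * e1[1])
      th <- theta[i - 2]; ph <- phi[i - 3] + pi
      # the +pi phase puts phi = 0 at trans (alternating planar zigzag),
      # matching the package's dihedral convention
      pos[i, ] <- pos[i - 1, ] + l[i - 1] *
        (cos(th) * e1 + sin(th) * (cos(ph) * e2 + sin(ph) * nv))
    }
  }
  pos
}

# Wrap a coordinate matrix into an hnp_state (velocities zero).
make_state <- function(pos, classes = rep("H", nrow(pos)), mass = 110) {
  structure(list(
    positions = pos,
    velocities = matrix(0, nrow(pos), 3),
    masses = rep(mass, nrow(pos)),
    sequence = structure(classes, unit = "explicit", class = "hnp_sequence"),
    time = 0), class = "hnp_state")
}

# A compact-but-not-overlapping random blob used for nonbonded tests:
# random walk rescaled into a ball so many pairs sit inside the cutoff.
random_blob <- function(n, seed, radius = 0.45) {
  set.seed(seed)
  pos <- matrix(rnorm(3 * n), n, 3)
  pos <- pos / sqrt(rowSums(pos^2)) * radius * runif(n)^(1 / 3)
  # keep pairs from deep overlap
  pos + matrix(rnorm(3 * n, sd = 0.02), n, 3)
}

# O(N^2) nonbonded oracle built on pair_potential(), independent of the
# C++ summation path.
nonbonded_oracle <- function(state, ff = forcefield()) {
  pos <- state$positions
  cls <- unclass(state$sequence)
  n <- nrow(pos)
  tot <- 0
  for (i in seq_len(n - 4)) {
    for (j in (i + 4):n) {
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      tot <- tot + pair_potential(cls[i], cls[j], r, ff)
    }
  }
  tot
}

# Exhaustive stem oracle: scan every maximal all-trans run by hand.
stems_oracle <- function(labels, min_stem = 4L) {
  out <- integer(0)
  run <- 0L
  for (lab in c(labels, "gauche")) {  # sentinel flushes the last run
    if (lab == "trans") run <- run + 1L
    else {
      if (run >= min_stem) out <- c(out, run)
      run <- 0L
    }
  }
  out
}

# Brute-force contact oracle.
contacts_oracle <- function(pos, Rcut = 0.65, lcut = 3L) {
  n <- nrow(pos)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i > lcut &&
          sqrt(sum((pos[i, ] - pos[j, ])^2)) <= Rcut) cnt <- cnt + 1L
    }
  }
  cnt
}

# Random rigid rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Minimal synthetic trajectory wrapper for analysis-level tests.
fake_trajectory <- function(frames_list, Tstar = 1.0, classes = NULL,
                            dt = 2.5, stride = 1L) {
  n <- nrow(frames_list[[1]])
  if (is.null(classes)) classes <- rep("H", n)
  arr <- array(0, c(length(frames_list), n, 3))
  for (i in seq_along(frames_list)) arr[i, , ] <- frames_list[[i]]
  steps <- (seq_along(frames_list) - 1L) * stride
  samples <- data.frame(step = steps, stretch = 0, bend = 0, torsion = 0,
                        nonbonded = 0, potential = 0, kinetic = 0,
                        T_inst = 0, xi = 0, Tstar_target = Tstar, leg = 1L)
  structure(list(
    frames = arr,
    frame_info = data.frame(step = steps, time_ps = steps * dt * 1e-3,
                            Tstar_target = Tstar, leg = 1L),
    samples = samples,
    final_state = make_state(frames_list[[length(frames_list)]], classes),
    sequence = structure(classes, unit = "explicit", class = "hnp_sequence"),
    protocol = run_protocol(data.frame(Tstar = Tstar, steps = max(steps) + 1L),
                            dt = dt, snapshot_stride = stride,
                            sample_stride = stride),
    ff = forcefield()), class = "hnp_trajectory")
}
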