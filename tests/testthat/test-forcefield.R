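ff <- forcefield()

test_that("force-field defaults match the published parameter set", {
  expect_equal(ff$l0, 0.153)
  expect_equal(ff$kd, 7e4)
  expect_equal(ff$theta0, 1.231)
  expect_equal(ff$ktheta, 100)
  expect_equal(ff$kphi, 2.0)
  expect_equal(ff$sigma, 0.3624)
  expect_equal(ff$eps_h, 0.1984)
  expect_equal(ff$Rc, 0.95)
  em <- ff$epsilon_matrix / ff$eps_h
  expect_equal(unname(em["H", ]), c(1, 2 / 3, 7 / 12))
  expect_equal(unname(em["N", ]), c(2 / 3, 1 / 3, 1 / 4))
  expect_equal(unname(em["P", ]), c(7 / 12, 1 / 4, 1 / 6))
  expect_equal(unname(diag(ff$lambda_matrix)), c(1, 0, -1))
  expect_true(isSymmetric(unname(ff$epsilon_matrix)))
  expect_true(isSymmetric(unname(ff$lambda_matrix)))
})

test_that("stretch energy is harmonic in bond displacements", {
  pos <- chain_from_internal(6)
  st <- make_state(pos)
  expect_equal(stretch_energy(st, ff), 0, tolerance = 1e-12)

  # displace the last bead 0.01 nm along its bond: 0.5 * 7e4 * 1e-4 = 3.5
  b <- pos[6, ] - pos[5, ]
  pos2 <- pos
  pos2[6, ] <- pos[6, ] + 0.01 * b / sqrt(sum(b^2))
  st2 <- make_state(pos2)
  expect_equal(stretch_energy(st2, ff), 3.5, tolerance = 1e-9)

  # doubling every displacement quadruples the energy
  pos4 <- pos
  pos4[6, ] <- pos[6, ] + 0.02 * b / sqrt(sum(b^2))
  expect_equal(stretch_energy(make_state(pos4), ff),
               4 * stretch_energy(st2, ff), tolerance = 1e-9)
})

test_that("bend energy is harmonic in the deflection angle", {
  st0 <- make_state(chain_from_internal(7))
  expect_equal(bend_energy(st0, ff), 0, tolerance = 1e-10)

  # one angle displaced by +0.1 rad: 0.5 * 100 * 0.01 = 0.5
  th <- rep(ff$theta0, 5); th[3] <- ff$theta0 + 0.1
  st1 <- make_state(chain_from_internal(7, theta = th))
  expect_equal(bend_energy(st1, ff), 0.5, tolerance = 1e-9)

  # rigid rotation leaves it unchanged
  r <- random_rotation(7)
  st_rot <- make_state(st1$positions %*% t(r))
  expect_equal(bend_energy(st_rot, ff), bend_energy(st1, ff),
               tolerance = 1e-9)
})

test_that("torsion term has trans/gauche minima and barrier kphi", {
  # planar all-trans zigzag: every dihedral at the trans minimum
  st0 <- make_state(chain_from_internal(10))
  expect_equal(torsion_energy(st0, ff), 0, tolerance = 1e-10)

  # N = 5 has exactly 2 dihedral terms
  phi <- seq(-pi, pi, length.out = 2001)
  one_dih <- vapply(phi, function(p)
    torsion_energy(make_state(chain_from_internal(5, phi = c(p, 0))), ff),
    numeric(1))
  # gauche minima at +-2pi/3, maximum kphi at the cis barrier
  expect_equal(max(one_dih), ff$kphi, tolerance = 1e-6)
  expect_equal(abs(phi[which.max(one_dih)]), pi, tolerance = 2e-3)
  gau <- torsion_energy(make_state(chain_from_internal(5, phi = c(2 * pi / 3, 0))), ff)
  expect_equal(gau, 0, tolerance = 1e-9)

  # term count: N = 5 -> 2 dihedrals, each contributing kphi/2 * (1 - cos 3phi)
  both <- torsion_energy(make_state(chain_from_internal(5, phi = c(pi / 3, pi / 3))), ff)
  expect_equal(both, 2 * 0.5 * ff$kphi * (1 - cos(pi)), tolerance = 1e-9)
})

test_that("pair potential reproduces the Lennard-Jones analytics", {
  # H-H crosses zero at sigma (unshifted)
  expect_equal(pair_potential("H", "H", ff$sigma, ff, shifted = FALSE), 0,
               tolerance = 1e-12)
  # depth at the minimum equals -eps_h; located at 2^(1/6) sigma
  opt <- optimize(function(r) pair_potential("H", "H", r, ff, shifted = FALSE),
                  c(0.2, 0.95), tol = 1e-10)
  expect_equal(opt$objective, -ff$eps_h, tolerance = 1e-8)
  expect_equal(opt$minimum, 2^(1 / 6) * ff$sigma, tolerance = 1e-5)

  # P-P (Lambda = -1) is positive and strictly decreasing inside the cutoff
  r <- seq(0.25, ff$Rc, length.out = 400)
  upp <- pair_potential("P", "P", r, ff, shifted = FALSE)
  expect_true(all(upp > 0))
  expect_true(all(diff(upp) < 0))

  # beyond the cutoff everything is zero; shifting makes it continuous there
  expect_equal(pair_potential("H", "H", ff$Rc + 1e-9, ff), 0)
  expect_equal(pair_potential("H", "H", ff$Rc - 1e-9, ff, shifted = TRUE), 0,
               tolerance = 1e-6)
  expect_error(pair_potential("H", "H", 0), "positive")
})

test_that("nonbonded energy equals the brute-force pair oracle", {
  # N = 5: exactly one eligible pair (1,5)
  pos <- chain_from_internal(5)
  st <- make_state(pos)
  expect_equal(nonbonded_energy(st, ff), nonbonded_oracle(st, ff),
               tolerance = 1e-12)

  # straight chain, all eligible pairs far beyond the cutoff
  straight <- cbind(0.3 * (0:4), 0, 0)
  expect_equal(nonbonded_energy(make_state(straight), ff), 0)

  # dense random blobs up to N = 60, mixed sequences
  for (n in c(12, 30, 60)) {
    blob <- random_blob(n, seed = n)
    cls <- sample(residue_classes, n, replace = TRUE)
    stb <- make_state(blob, cls)
    expect_equal(nonbonded_energy(stb, ff), nonbonded_oracle(stb, ff),
                 tolerance = 1e-12, label = paste("blob n =", n))
  }
})

test_that("analytic forces match finite differences and conserve momenta", {
  st <- initial_configuration(build_sequence("H3N1P1", 20), seed = 5,
                              Tstar = 1.0)
  res <- total_energy_and_forces(st, ff)
  f <- res$forces
  h <- 1e-6
  num <- matrix(0, 20, 3)
  for (i in 1:20) {
    for (k in 1:3) {
      sp <- st; sp$positions[i, k] <- sp$positions[i, k] + h
      sm <- st; sm$positions[i, k] <- sm$positions[i, k] - h
      num[i, k] <- -(energy_breakdown(sp, ff)$total -
                       energy_breakdown(sm, ff)$total) / (2 * h)
    }
  }
  expect_lt(max(abs(num - f)) / max(abs(f)), 1e-4)

  # Newton's third law and zero net torque about the center of mass
  expect_lt(max(abs(colSums(f))), 1e-8)
  com <- colMeans(st$positions)
  rr <- sweep(st$positions, 2, com)
  tq <- colSums(cbind(rr[, 2] * f[, 3] - rr[, 3] * f[, 2],
                      rr[, 3] * f[, 1] - rr[, 1] * f[, 3],
                      rr[, 1] * f[, 2] - rr[, 2] * f[, 1]))
  expect_lt(max(abs(tq)), 1e-8)

  # at the bonded minimum every bonded force component vanishes
  # (with sigma = 0.3624 nm and l0 = 0.153 nm any |i-j| = 4 pair sits inside
  # the 0.95 nm cutoff, so the LJ term is silenced to isolate the minimum)
  ff_bonded <- forcefield(epsilon_matrix = 1e-14 * forcefield()$epsilon_matrix)
  st_min <- make_state(chain_from_internal(10))
  expect_lt(max(abs(total_energy_and_forces(st_min, ff_bonded)$forces)), 1e-7)
})

test_that("energy terms are invariant under rigid motion", {
  st <- initial_configuration(build_sequence("H4N2P2", 24), seed = 9,
                              Tstar = 1.0)
  e0 <- energy_breakdown(st, ff)
  for (s in 1:3) {
    r <- random_rotation(s)
    shift <- matrix(rnorm(3), 1)
    st2 <- st
    st2$positions <- sweep(st$positions %*% t(r), 2, -shift)
    e1 <- energy_breakdown(st2, ff)
    for (term in c("stretch", "bend", "torsion", "nonbonded", "total"))
      expect_equal(e1[[term]], e0[[term]], tolerance = 1e-9,
                   label = paste(term, "seed", s))
  }
})

test_that("energy breakdown is internally consistent", {
  st <- initial_configuration(build_sequence("H3N1P1", 30), seed = 2,
                              Tstar = 1.0)
  e <- energy_breakdown(st, ff)
  expect_equal(e$total, e$stretch + e$bend + e$torsion + e$nonbonded,
               tolerance = 1e-10)
  expect_equal(e$per_bond_stretch_bend, (e$stretch + e$bend) / 29)
  expect_equal(e$per_angle, e$bend / 28)
  expect_equal(e$per_dihedral, e$torsion / 27)
  expect_equal(e$per_bond_total, e$total / 29)
})

test_that("force-field JSON round trip preserves every parameter", {
  path <- withr::local_tempfile(fileext = ".json")
  custom <- forcefield(kphi = 3.5, eps_h = 0.25, shift_at_cutoff = FALSE)
  write_forcefield(custom, path)
  back <- read_forcefield(path)
  expect_equal(back[names(back) != "epsilon_matrix"],
               custom[names(custom) != "epsilon_matrix"], tolerance = 1e-12)
  expect_equal(unname(back$epsilon_matrix), unname(custom$epsilon_matrix),
               tolerance = 1e-12)
})

test_that("overlapping beads raise a singular-configuration error", {
  pos <- chain_from_internal(6)
  pos[6, ] <- pos[1, ] + 1e-6
  expect_error(total_energy_and_forces(make_state(pos), ff), "singular")
})
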