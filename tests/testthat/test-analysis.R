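test_that("gyration radius matches hand-computed values and the trace identity", {
  # single bead: coincides with its center of mass
  g1 <- gyration(matrix(c(0.3, -0.1, 2), 1, 3))
  expect_equal(g1$Rg, 0)

  # two beads 0.4 nm apart: Rg = 0.2, all of it on the long axis
  g2 <- gyration(rbind(c(0, 0, 0), c(0.4, 0, 0)))
  expect_equal(g2$Rg, 0.2, tolerance = 1e-12)
  expect_equal(c(g2$Rgx, g2$Rgy, g2$Rgz), c(0, 0, 0.2), tolerance = 1e-9)

  # trace identity and component ordering on random frames
  for (s in 1:5) {
    pos <- random_blob(40, seed = 100 + s)
    g <- gyration(pos)
    expect_equal(g$Rg^2, g$Rgx^2 + g$Rgy^2 + g$Rgz^2, tolerance = 1e-10)
    expect_true(g$Rgx <= g$Rgy && g$Rgy <= g$Rgz)
    # direct formula oracle for Rg
    rc <- colMeans(pos)
    expect_equal(g$Rg, sqrt(mean(rowSums(sweep(pos, 2, rc)^2))),
                 tolerance = 1e-12)
    # rotation leaves Rg and components unchanged
    g_rot <- gyration(pos %*% t(random_rotation(s)))
    expect_equal(c(g_rot$Rgx, g_rot$Rgy, g_rot$Rgz),
                 c(g$Rgx, g$Rgy, g$Rgz), tolerance = 1e-9)
  }
})

test_that("orientational order hits the parallel, perpendicular and random limits", {
  # straight chain along one axis: P = 1 (long axis is the chain axis)
  straight <- cbind(0.153 * (0:49), 0, 0)
  expect_equal(orientational_order(straight), 1, tolerance = 1e-12)

  # bonds perpendicular to an explicit axis: P = -0.5
  expect_equal(orientational_order(straight, axis = c(0, 0, 1)), -0.5,
               tolerance = 1e-12)

  # many isotropic bonds against a fixed external axis: |P| < 0.01
  set.seed(4)
  nb <- 1e5
  dirs <- matrix(rnorm(3 * (nb + 1)), nb + 1, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  walk <- apply(dirs * 0.153, 2, cumsum)
  expect_lt(abs(orientational_order(walk, axis = c(0, 0, 1))), 0.01)

  # equals a direct per-bond loop oracle
  pos <- random_blob(30, seed = 77)
  axis <- gyration(pos)$axes[, 3]
  ca <- numeric(29)
  for (i in 1:29) {
    b <- pos[i + 1, ] - pos[i, ]
    ca[i] <- sum(b * axis) / sqrt(sum(b^2))
  }
  expect_equal(orientational_order(pos), mean((3 * ca^2 - 1) / 2),
               tolerance = 1e-12)

  # literal N-2 bond variant drops the first bond
  expect_equal(orientational_order(pos, all_bonds = FALSE),
               mean(((3 * ca^2 - 1) / 2)[-1]), tolerance = 1e-12)
})

test_that("dihedral classification separates trans from gauche", {
  # all-trans zigzag of N = 10: 7 trans labels
  zz <- chain_from_internal(10)
  expect_equal(dihedral_states(zz), rep("trans", 7))
  expect_lt(max(abs(dihedral_angles(zz))), 1e-9)

  # rotate dihedral 3 to 2pi/3: that position (only) becomes gauche
  phi <- rep(0, 7); phi[3] <- 2 * pi / 3
  st <- chain_from_internal(10, phi = phi)
  expect_equal(dihedral_states(st),
               replace(rep("trans", 7), 3, "gauche"))
  expect_equal(dihedral_angles(st)[3], 2 * pi / 3, tolerance = 1e-9)

  # the trans boundary is |phi| = pi/3
  st_edge <- chain_from_internal(5, phi = c(pi / 3 - 1e-6, pi / 3 + 1e-6))
  expect_equal(dihedral_states(st_edge), c("trans", "gauche"))

  # labels are internal coordinates: invariant under rigid rotation
  r <- random_rotation(12)
  expect_equal(dihedral_states(st %*% t(r)), dihedral_states(st))
})

test_that("stems are maximal all-trans runs of at least four bonds", {
  t <- "trans"; g <- "gauche"
  expect_equal(stems(c(t, t, t, t, g)), 4L)
  expect_equal(stems(c(t, t, t, g, t)), integer(0))
  expect_equal(stems(c(rep(t, 12), g, rep(t, 5))), c(12L, 5L))
  expect_equal(stems(rep(g, 6)), integer(0))
  expect_equal(stems(c(t, t, t), min_stem = 3L), 3L)

  # property: agrees with the exhaustive run-enumeration oracle
  set.seed(31)
  for (case in 1:300) {
    labels <- sample(c(t, g), sample(4:40, 1), replace = TRUE,
                     prob = c(0.7, 0.3))
    expect_identical(stems(labels), stems_oracle(labels),
                     label = paste("case", case))
  }
})

test_that("stem distributions pool frames and normalize", {
  # frozen all-trans chain: a single stem of length N - 3 per frame
  zz <- chain_from_internal(20)
  d <- stem_distribution(list(zz, zz, zz))
  expect_equal(d$Ntr, 17L)
  expect_equal(d$probability, 1)
  expect_equal(attr(d, "n_stems_observed"), 3L)

  # all-gauche chain: empty histogram
  allg <- chain_from_internal(12, phi = 2 * pi / 3)
  d0 <- stem_distribution(allg)
  expect_equal(nrow(d0), 0L)
  expect_equal(attr(d0, "n_stems_observed"), 0L)

  # merging frame sets equals the count-weighted merge
  mixed <- chain_from_internal(20, phi = replace(rep(0, 17), 9, 2 * pi / 3))
  dA <- stem_distribution(list(zz))          # one stem: 17
  dB <- stem_distribution(list(mixed))       # two stems: 8 and 8? computed below
  dAB <- stem_distribution(list(zz, mixed))
  pooled <- c(rep(dA$Ntr, dA$probability * attr(dA, "n_stems_observed")),
              rep(dB$Ntr, round(dB$probability * attr(dB, "n_stems_observed"))))
  tab <- table(pooled)
  expect_equal(dAB$Ntr, as.integer(names(tab)))
  expect_equal(dAB$probability, as.numeric(tab) / sum(tab), tolerance = 1e-12)
})

test_that("contact counting matches the brute-force oracle", {
  # straight sparse chain: no eligible pair inside the cutoff
  straight <- cbind(0.3 * (0:9), 0, 0)
  expect_equal(contact_count(straight), 0L)

  # hairpin: two 6-bead strands 0.5 nm apart
  hairpin <- rbind(cbind(0.38 * (0:5), 0, 0),
                   cbind(0.38 * (5:0), 0.5, 0))
  expect_equal(contact_count(hairpin), contacts_oracle(hairpin))
  expect_gt(contact_count(hairpin), 0L)

  # random frames: exact agreement, and monotonicity in Rcut
  for (s in 1:5) {
    pos <- random_blob(45, seed = 200 + s)
    expect_equal(contact_count(pos), contacts_oracle(pos))
    expect_equal(contact_count(pos, Rcut = 0.5, lcut = 5L),
                 contacts_oracle(pos, Rcut = 0.5, lcut = 5L))
    expect_lte(contact_count(pos, Rcut = 0.45), contact_count(pos, Rcut = 0.65))
  }

  # pair list agrees with the count and respects the separation rule
  cp <- contact_pairs(hairpin)
  expect_equal(nrow(cp), contact_count(hairpin))
  expect_true(all(cp$j - cp$i > 3))
  expect_true(all(cp$distance <= 0.65))
})

test_that("sweep_summary of a degenerate ensemble equals single-frame values", {
  zz <- chain_from_internal(30)
  traj <- fake_trajectory(list(zz, zz, zz, zz), Tstar = 0.7)
  s <- sweep_summary(traj, equilibration_fraction = 0.25, n_boot = 50)
  g <- gyration(zz)
  expect_equal(s$Rg, g$Rg, tolerance = 1e-12)
  expect_equal(s$Rgz, g$Rgz, tolerance = 1e-12)
  expect_equal(s$P, orientational_order(zz), tolerance = 1e-12)
  expect_equal(s$contacts, contact_count(zz))
  expect_equal(s$Rg_se, 0, tolerance = 1e-12)
  expect_equal(s$Tstar, 0.7)
})
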