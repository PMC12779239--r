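test_that("Coulomb and Lennard-Jones closed forms are exact", {
  tb <- two_bead_traj(0.5)  # +1/-1 e, no LJ
  e <- group_interaction_energy(tb$trajectory, "receptor", "ligand")
  expect_equal(e$total[1], -277.870916, tolerance = 1e-9)

  lj <- function(sep, sigma = 0.3, eps = 0.5) {
    tb <- two_bead_traj(sep, charge = c(0, 0), sigma = sigma, epsilon = eps)
    group_interaction_energy(tb$trajectory, "receptor", "ligand")$total[1]
  }
  expect_equal(lj(0.3), 0, tolerance = 1e-10)              # zero crossing at sigma
  expect_equal(lj(2^(1 / 6) * 0.3), -0.5, tolerance = 1e-10)  # minimum -eps
  # all charges zero, no LJ
  tb0 <- two_bead_traj(0.5, charge = c(0, 0), epsilon = 0)
  expect_equal(group_interaction_energy(tb0$trajectory, "receptor",
                                        "ligand")$total[1], 0)
})

test_that("any-frame contact gating uses inclusive 0.6 nm over all frames", {
  tb <- two_bead_traj(0.59)
  expect_equal(nrow(anyframe_contact_pairs(tb$trajectory, "receptor",
                                           "ligand")), 1)
  tb2 <- two_bead_traj(0.7)
  expect_equal(nrow(anyframe_contact_pairs(tb2$trajectory, "receptor",
                                           "ligand")), 0)
  # 0.7 nm in all frames except one at 0.55 -> included
  top <- tb$topology
  frames <- lapply(c(0.7, 0.7, 0.55, 0.7), function(s) {
    rbind(c(0, 0, 0), c(s, 0, 0))
  })
  tr <- traj_from_frames(top, frames)
  expect_equal(nrow(anyframe_contact_pairs(tr, "receptor", "ligand")), 1)
  expect_error(anyframe_contact_pairs(tb$trajectory, 1:2, 2:2),
               class = "mdbind_selection_error")
})

test_that("pairwise energies are additive against the group total", {
  spec <- toy_complex_spec(n_frames = 100, seed = 3)
  tc <- gen_toy_complex(spec)
  tr <- tc$parent$trajectory
  allpairs <- expand.grid(res_a = 1:25, res_b = 26:50)
  free <- nonbonded_params(cutoff = Inf)
  pe <- pair_energy_series(tr, allpairs, free)
  ge <- group_interaction_energy(tr, "receptor", "ligand", free)
  expect_lt(abs(sum(pe$total) - mean(ge$total)) / abs(mean(ge$total)), 1e-6)
  # table is restricted to the requested (gated) pairs
  gates <- anyframe_contact_pairs(tr, "receptor", "ligand")
  pe2 <- pair_energy_series(tr, gates)
  expect_equal(nrow(pe2), nrow(gates))
})

test_that("SASA matches sphere analytics and is rigid-motion invariant", {
  top <- bead_topology(1)
  s <- sasa_shrake_rupley(frame(matrix(0, 1, 3)), top, selection = 1,
                          radii = 0.15, probe = 0.14, n_points = 960)
  expect_equal(s$total, 4 * pi * 0.29^2, tolerance = 0.01)

  # fully buried atom: small sphere at the center of a larger one
  top2 <- bead_topology(2)
  s2 <- sasa_shrake_rupley(frame(rbind(c(0, 0, 0), c(0.02, 0, 0))), top2,
                           selection = 1:2, radii = c(0.1, 0.4), probe = 0.14)
  expect_equal(s2$per_atom$area_nm2[1], 0)

  # far-apart atoms are additive
  s3 <- sasa_shrake_rupley(frame(rbind(c(0, 0, 0), c(5, 0, 0))), top2,
                           selection = 1:2, radii = c(0.15, 0.2), probe = 0.14)
  expect_equal(s3$total, 4 * pi * (0.29^2 + 0.34^2), tolerance = 0.01)

  # rigid transform invariance (deterministic point set moves with the atoms
  # only through distances, so areas match to rounding)
  set.seed(4)
  X <- matrix(rnorm(18, sd = 0.3), 6, 3)
  top6 <- bead_topology(6)
  Rm <- random_rotation()
  a1 <- sasa_shrake_rupley(frame(X), top6, 1:6, radii = rep(0.15, 6))$total
  a2 <- sasa_shrake_rupley(frame(sweep(X %*% Rm, 2, c(1, 2, 3), `+`)), top6,
                           1:6, radii = rep(0.15, 6))$total
  expect_equal(a1, a2, tolerance = 1e-6)

  # point-count convergence: 960 -> 3840 changes the total by < 0.5%
  a960 <- sasa_shrake_rupley(frame(X), top6, 1:6, radii = rep(0.15, 6),
                             n_points = 960)$total
  a3840 <- sasa_shrake_rupley(frame(X), top6, 1:6, radii = rep(0.15, 6),
                              n_points = 3840)$total
  expect_lt(abs(a960 - a3840) / a3840, 0.005)

  expect_error(sasa_shrake_rupley(frame(X), top6, 1:6, radii = rep(0.1, 3)),
               class = "mdbind_format_error")
})

test_that("apolar term reproduces the printed constants and algebra", {
  expect_equal(apolar_energy(0), 3.84928, tolerance = 1e-9)
  expect_equal(apolar_energy(1), 6.117008, tolerance = 1e-9)
  expect_error(apolar_energy(-1), class = "mdbind_spec_error")
  # binding difference: b enters once, negatively
  sas_c <- 3.2; sas_a <- 2.0; sas_b <- 1.5
  dE <- apolar_energy(sas_c) - apolar_energy(sas_a) - apolar_energy(sas_b)
  gamma <- 0.00542 * 4.184 * 100
  expect_equal(dE, gamma * (sas_c - sas_a - sas_b) - 0.92 * 4.184,
               tolerance = 1e-9)
})

test_that("FD-PB solver approximates the Born ion and its monotonicity", {
  top <- bead_topology(1, charge = 1)
  fr <- frame(matrix(0, 1, 3))
  born <- function(eps_out, a = 0.2) {
    -138.935458 / (2 * a) * (1 - 1 / eps_out)
  }
  e <- polar_energy_fdpb(fr, top, pb_settings(spacing = 0.05, eps_solute = 1,
                                              padding = 1.0), radii = 0.2)
  expect_equal(e, born(78.5), tolerance = 0.05)

  # zero charges -> 0 without a solve
  top0 <- bead_topology(1, charge = 0)
  expect_equal(polar_energy_fdpb(fr, top0, pb_settings(spacing = 0.1),
                                 radii = 0.2), 0)

  # |energy| increases monotonically with the solvent dielectric
  es <- vapply(c(2, 10, 78.5), function(eo) {
    polar_energy_fdpb(fr, top, pb_settings(spacing = 0.05, eps_solute = 1,
                                           eps_solvent = eo, padding = 0.8),
                      radii = 0.2)
  }, numeric(1))
  expect_true(all(diff(abs(es)) > 0))
  expect_true(all(es < 0))

  expect_error(polar_energy_fdpb(fr, top, pb_settings(spacing = 0.1,
                                                      padding = 0.1),
                                 radii = 0.2),
               class = "mdbind_spec_error")
})

test_that("MM/PBSA summary equals its component oracles and discriminates", {
  spec <- toy_complex_spec(n_frames = 60, seed = 6)
  tc <- gen_toy_complex(spec)
  tr <- tc$parent$trajectory
  summ <- mmpbsa_summary(tr, "receptor", "ligand", pb = NULL)
  # Delta E_SR equals the mean inter-group SR energy exactly
  ge <- group_interaction_energy(tr, "receptor", "ligand")
  expect_equal(summ$summary$mean[summ$summary$term == "E_SR"], mean(ge$total),
               tolerance = 1e-12)

  # identical parent/parent comparison: all differences zero
  summ2 <- mmpbsa_summary(tr, "receptor", "ligand", pb = NULL)
  expect_equal(summ$summary$mean, summ2$summary$mean)

  # mutant with closer opposite-charge interface binds more strongly
  summ_m <- mmpbsa_summary(tc$mutant$trajectory, "receptor", "ligand",
                           pb = NULL)
  expect_lt(summ_m$summary$mean[1], summ$summary$mean[1])

  expect_error(mmpbsa_summary(tr, "receptor", "ligand", pb = NULL,
                              dense_stride = 1000),
               class = "mdbind_insufficient_data_error")
})

test_that("interaction energies are invariant under global rigid motion", {
  spec <- toy_complex_spec(n_frames = 10, seed = 8)
  tc <- gen_toy_complex(spec)
  tr <- tc$parent$trajectory
  set.seed(9)
  Rm <- random_rotation()
  arr <- tr$replicas[[1]]$coords
  arr2 <- arr
  for (i in seq_len(dim(arr)[1])) {
    arr2[i, , ] <- sweep(arr[i, , ] %*% Rm, 2, c(3, -1, 2), `+`)
  }
  tr2 <- as_trajectory(arr2, tr$topology, times = tr$replicas[[1]]$time,
                       discard_ns = 0)
  e1 <- group_interaction_energy(tr, "receptor", "ligand")$total
  e2 <- group_interaction_energy(tr2, "receptor", "ligand")$total
  expect_equal(e1, e2, tolerance = 1e-9)
})
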