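test_that("Gaussian ensembles realize planted correlations and determinism", {
  n <- 5000
  tr <- gen_gaussian_ensemble(8, n, seed = 11,
                              correlations = data.frame(i = 3, j = 8, rho = 0.8))
  X <- tr$replicas[[1]]$coords
  # planted pair: empirical per-dimension Pearson r = 0.8 +/- 0.03
  for (d in 1:3) {
    expect_equal(cor(X[, 3, d], X[, 8, d]), 0.8, tolerance = 0.03 / 0.8)
  }
  # unplanted pairs: |r| < 3/sqrt(n)
  r0 <- abs(c(cor(X[, 1, 1], X[, 2, 1]), cor(X[, 4, 2], X[, 5, 2]),
              cor(X[, 6, 3], X[, 7, 3])))
  expect_true(all(r0 < 3 / sqrt(n)))

  tr2 <- gen_gaussian_ensemble(8, n, seed = 11,
                               correlations = data.frame(i = 3, j = 8, rho = 0.8))
  expect_identical(tr$replicas[[1]]$coords, tr2$replicas[[1]]$coords)

  expect_error(gen_gaussian_ensemble(3, 10, seed = 1,
                                     correlations = data.frame(i = 1, j = 2, rho = 1)),
               class = "mdbind_spec_error")
  # infeasible correlation triple is not positive definite
  bad <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3), rho = c(0.9, 0.9, -0.9))
  expect_error(gen_gaussian_ensemble(3, 10, seed = 1, correlations = bad),
               class = "mdbind_spec_error")
})

test_that("harmonic wells match kB*T/k per dimension and attach analytics", {
  # k chosen so kB*T = k at 310 K -> unit variance per dimension
  k310 <- phys_constants$kB * 310
  tr <- gen_harmonic_wells(2, k310, temperature = 310, n_frames = 20000,
                           seed = 5, spacing = 50)
  an <- attr(tr, "analytic")
  expect_equal(an$var_per_dim, rep(1, 2))
  v <- apply(tr$replicas[[1]]$coords, c(2, 3), var)
  expect_equal(mean(v), 1, tolerance = 0.05)
  # sample covariance converges to the analytic one element-wise
  X <- tr$replicas[[1]]$coords[, 1, ]
  offdiag <- cov(X)[upper.tri(diag(3))]
  expect_true(all(abs(offdiag) < 4 / sqrt(20000) * 3))

  expect_error(gen_harmonic_wells(2, c(1, -1), n_frames = 10, seed = 1),
               class = "mdbind_spec_error")
  expect_error(gen_harmonic_wells(2, 1, temperature = 0, n_frames = 10, seed = 1),
               class = "mdbind_spec_error")
})

test_that("toy complexes plant a controllable interface", {
  # no jitter: constant interface distance series
  spec0 <- toy_complex_spec(jitter_sd = 0, n_frames = 5, seed = 2)
  tc0 <- gen_toy_complex(spec0)
  ds <- residue_pair_distances(tc0$parent$trajectory,
                               data.frame(res_a = 1, res_b = 26))
  expect_equal(var(ds$series$distance_nm), 0)
  expect_equal(ds$series$distance_nm[1], 0.55, tolerance = 1e-12)

  # mutant moves the ligand bead closer -> more negative Coulomb
  spec <- toy_complex_spec(jitter_sd = 0, n_frames = 3)
  tc <- gen_toy_complex(spec)
  ep <- mean(group_interaction_energy(tc$parent$trajectory, "receptor",
                                      "ligand")$coulomb)
  em <- mean(group_interaction_energy(tc$mutant$trajectory, "receptor",
                                      "ligand")$coulomb)
  expect_lt(em, ep)

  # topologies and reference geometry differ at exactly the declared bead
  pp <- tc$parent$trajectory$replicas[[1]]$coords[1, , ]
  mm <- tc$mutant$trajectory$replicas[[1]]$coords[1, , ]
  moved <- which(rowSums(abs(pp - mm)) > 0)
  expect_equal(moved, 26)
  expect_identical(tc$parent$topology$atoms$charge,
                   tc$mutant$topology$atoms$charge)

  expect_error(gen_toy_complex(toy_complex_spec(bridge_gap = 0.01, n_frames = 2)),
               class = "mdbind_spec_error")
})

test_that("planted paths satisfy their geometric and statistical contract", {
  gp <- gen_planted_path(10, c(1, 4, 7, 10), 0.9, 0.1, n_frames = 2000,
                         seed = 3)
  # path edges are contacts: heavy-atom distance < 0.5 nm in >= 70% of frames
  X <- gp$trajectory$replicas[[1]]$coords
  for (k in 1:3) {
    a <- gp$path[k]; b <- gp$path[k + 1]
    d <- sqrt(rowSums((X[, a, ] - X[, b, ])^2))
    expect_gte(mean(d < 0.5), 0.70)
  }
  # planted path-edge correlation equals rho_on
  expect_equal(gp$correlation[1, 4], 0.9, tolerance = 1e-9)
  # degenerate planting rho_on = rho_off is valid
  expect_silent(gen_planted_path(6, c(1, 3, 6), 0.5, 0.5, n_frames = 200,
                                 seed = 1))
  expect_error(gen_planted_path(10, c(1, 4, 7, 10), 0.1, 0.9, n_frames = 100,
                                seed = 1),
               class = "mdbind_spec_error")
  gp2 <- gen_planted_path(10, c(1, 4, 7, 10), 0.9, 0.1, n_frames = 2000,
                          seed = 3)
  expect_identical(gp$trajectory$replicas[[1]]$coords,
                   gp2$trajectory$replicas[[1]]$coords)
})

test_that("work sets satisfy the Gaussian Crooks construction", {
  kB <- phys_constants$kB
  ws <- gen_work_sets(-5, 2, 310, 10000, 10000, seed = 4)
  # Gaussian Jarzynski identity: forward mean = dG + beta sigma^2 / 2
  expect_equal(mean(ws$forward), -5 + 4 / (2 * kB * 310), tolerance = 0.03)
  expect_equal(mean(ws$backward), 5 + 4 / (2 * kB * 310), tolerance = 0.03)
  expect_equal(sd(ws$forward), 2, tolerance = 0.05)

  # distributional check (KS) against the stated normal
  ks <- ks.test(ws$forward, "pnorm", -5 + 4 / (2 * kB * 310), 2)
  expect_gt(ks$p.value, 0.01)

  # reversible limit
  ws0 <- gen_work_sets(-5, 1e-9, 310, 100, 100, seed = 1)
  expect_equal(max(abs(ws0$forward + 5)), 0, tolerance = 1e-7)

  expect_identical(gen_work_sets(-5, 2, 310, 50, 50, seed = 9)$forward,
                   gen_work_sets(-5, 2, 310, 50, 50, seed = 9)$forward)
  expect_error(gen_work_sets(-5, 0, 310, 10, 10, seed = 1),
               class = "mdbind_spec_error")
  expect_error(gen_work_sets(-5, 1, 310, 1, 10, seed = 1),
               class = "mdbind_spec_error")
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(gen_work_sets(-5, 2, 310, 10, 10, seed = 1))
  after <- rnorm(1)
  expect_identical(before, after)
})
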