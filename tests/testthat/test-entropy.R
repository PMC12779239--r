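test_that("Schlitter entropy hits its closed-form argument and zero limit", {
  kB <- phys_constants$kB
  alpha <- mdbind:::schlitter_alpha(310)
  # one bead fluctuating only along x with m*var chosen so the Schlitter
  # argument is e^2 - 1: S = kB/2 * ln(e^2) = kB
  m <- 12.011
  v_target <- (exp(2) - 1) / (alpha * m)
  set.seed(41)
  x <- rnorm(4000)
  x <- (x - mean(x)) / sd(x) * sqrt(v_target)  # exact sample variance
  top <- bead_topology(1, mass = m)
  frames <- lapply(x, function(xi) matrix(c(xi, 0, 0), 1, 3))
  tr <- traj_from_frames(top, frames)
  er <- suppressWarnings(schlitter_entropy(tr, selection = 1,
                                           temperature = 310,
                                           superpose = FALSE))
  expect_equal(er$S, kB, tolerance = 1e-6)
  expect_equal(er$minus_TS, -310 * kB, tolerance = 1e-6)

  # zero-variance trajectory: S = 0
  tr0 <- traj_from_frames(top, rep(list(matrix(1, 1, 3)), 200))
  er0 <- suppressWarnings(schlitter_entropy(tr0, selection = 1,
                                            superpose = FALSE))
  expect_equal(er0$S, 0)
})

test_that("Schlitter matches harmonic analytics and bounds the QHO entropy", {
  k <- c(50, 200, 1000)
  tr <- gen_harmonic_wells(3, k, 310, n_frames = 20000, seed = 42)
  an <- attr(tr, "analytic")
  alpha <- mdbind:::schlitter_alpha(310)
  S_exact <- 0.5 * phys_constants$kB *
    sum(3 * log1p(alpha * an$mass * an$var_per_dim))
  er <- schlitter_entropy(tr, selection = 1:3, temperature = 310,
                          superpose = FALSE)
  expect_equal(er$S, S_exact, tolerance = 0.02)

  # upper-bound property vs the quantum harmonic oscillator, closed forms
  for (kk in c(5, 50, 500, 5000)) {
    omega2 <- kk / 12.011
    v <- phys_constants$kB * 310 / kk
    S_schl <- 0.5 * phys_constants$kB * 3 * log1p(alpha * 12.011 * v)
    expect_gte(S_schl, qho_entropy(kk, 12.011, 310))
  }
  # and for the sampled estimate in the quantum-sensitive regime
  trq <- gen_harmonic_wells(3, 5e4, 310, n_frames = 20000, seed = 43)
  erq <- schlitter_entropy(trq, selection = 1:3, superpose = FALSE)
  expect_gte(erq$S, qho_entropy(rep(5e4, 3), 12.011, 310))
})

test_that("entropy is invariant under rigid transformation of all frames", {
  tr <- gen_harmonic_wells(4, 100, 310, n_frames = 2000, seed = 44)
  arr <- tr$replicas[[1]]$coords
  set.seed(45)
  Rm <- random_rotation()
  arr2 <- arr
  for (i in seq_len(dim(arr)[1])) {
    arr2[i, , ] <- sweep(arr[i, , ] %*% Rm, 2, c(1, 2, -1), `+`)
  }
  tr2 <- as_trajectory(arr2, tr$topology, times = tr$replicas[[1]]$time,
                       discard_ns = 0)
  e1 <- schlitter_entropy(tr, selection = 1:4)
  e2 <- schlitter_entropy(tr2, selection = 1:4)
  expect_equal(e1$S, e2$S, tolerance = 1e-6)
})

test_that("binding-entropy cycle is plain algebra with the right sign", {
  expect_equal(entropy_cycle(2, c(1, 0.5), 2, c(1, 0.5))$minus_T_dd_S, 0)
  # hand-set values at T = 310
  cyc <- entropy_cycle(2, c(1, 0.5), 2, c(1, 0.9), temperature = 310)
  expect_equal(cyc$delta_s_1, 0.5)
  expect_equal(cyc$delta_s_2, 0.1)
  expect_equal(cyc$minus_T_dd_S, -310 * 0.4)
  # a more ordered complex in system 1 (smaller S gain) -> positive penalty
  cyc2 <- entropy_cycle(1.2, 1.5, 2.0, 1.5, temperature = 310)
  expect_gt(cyc2$minus_T_dd_S, 0)
})

test_that("BAR and CGI recover planted free energies", {
  ws <- gen_work_sets(-5, 2, 310, 4000, 4000, seed = 46)
  b <- bar_delta_g(ws, n_boot = 50, seed = 1)
  expect_equal(b$delta_g, -5, tolerance = 0.1 / 5)
  cg <- bar_delta_g(ws, method = "cgi", n_boot = 50, seed = 1)
  expect_equal(cg$delta_g, -5, tolerance = 0.1 / 5)
  # BAR and CGI agree within twice the combined bootstrap uncertainty
  expect_lt(abs(b$delta_g - cg$delta_g),
            2 * (b$uncertainty + cg$uncertainty))

  # reversible limit: dG = mean forward work
  ws0 <- gen_work_sets(-7, 1e-9, 310, 50, 50, seed = 2)
  b0 <- bar_delta_g(ws0, n_boot = 10, seed = 1)
  expect_equal(b0$delta_g, mean(ws0$forward), tolerance = 1e-6)

  # antisymmetry: swapping directions negates dG
  swap <- work_set(ws$backward, ws$forward, 310)
  bs <- bar_delta_g(swap, n_boot = 10, seed = 1)
  expect_equal(bs$delta_g, -b$delta_g, tolerance = 1e-9)

  expect_error(bar_delta_g(work_set(1, c(1, 2))),
               class = "mdbind_insufficient_data_error")
  # non-overlapping distributions attach a warning
  far <- work_set(rnorm(50, 100, 0.1), rnorm(50, 100, 0.1), 310)
  expect_warning(bf <- bar_delta_g(far, n_boot = 5, seed = 1), "overlap")
  expect_true(bf$overlap_warning)
})

test_that("the thermodynamic cycle combines legs exactly", {
  l1 <- list(delta_g = -10, uncertainty = 1)
  l2 <- list(delta_g = -6, uncertainty = 1)
  cyc <- ddg_cycle(l1, l2)
  expect_equal(cyc$ddg, -4)
  expect_equal(cyc$uncertainty, sqrt(2))
  expect_equal(ddg_cycle(l1, l1)$ddg, 0)
  expect_error(ddg_cycle(l1, list(uncertainty = 1)),
               class = "mdbind_spec_error")

  # planted two-leg recovery
  b1 <- bar_delta_g(gen_work_sets(-10, 2, 310, 2000, 2000, seed = 47),
                    n_boot = 50, seed = 1)
  b2 <- bar_delta_g(gen_work_sets(-6, 2, 310, 2000, 2000, seed = 48),
                    n_boot = 50, seed = 1)
  cyc2 <- ddg_cycle(b1, b2)
  expect_lt(abs(cyc2$ddg - (-4)), 3 * cyc2$uncertainty + 0.2)
})

test_that("work tables round-trip through the two-column format", {
  ws <- gen_work_sets(-5, 2, 310, 20, 25, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_work_table(f, ws)
  ws2 <- read_work_table(f, 310)
  expect_equal(ws2$forward, ws$forward)
  expect_equal(ws2$backward, ws$backward)
})
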