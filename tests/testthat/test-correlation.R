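test_that("kNN MI matches the Gaussian closed form and is symmetric", {
  # 3-D Gaussian pair with per-dimension rho = 0.6:
  # I = 3 * (-1/2) * log(1 - 0.36) = 0.6694 nats
  tr <- gen_gaussian_ensemble(3, 5000, seed = 21,
                              correlations = data.frame(i = 1, j = 3, rho = 0.6))
  mi <- mi_matrix_knn(tr, k = 6, stride = 1, superpose = FALSE)
  I_exact <- -1.5 * log(1 - 0.36)
  expect_equal(mi[1, 3], I_exact, tolerance = 0.15)
  # independent nodes: MI within estimator bias of zero
  expect_lt(mi[1, 2], 0.05)
  expect_identical(mi[1, 3], mi[3, 1])
  expect_error(mi_matrix_knn(gen_gaussian_ensemble(3, 50, seed = 1),
                             stride = 1),
               class = "mdbind_insufficient_data_error")
})

test_that("generalized correlation transform obeys its limits", {
  m <- matrix(0, 2, 2)
  expect_equal(generalized_correlation(m)[1, 2], 0)
  m[1, 2] <- m[2, 1] <- 50
  expect_equal(generalized_correlation(m)[1, 2], 1, tolerance = 1e-10)
  m[1, 2] <- m[2, 1] <- -1.5 * log(1 - 0.36)
  expect_equal(generalized_correlation(m)[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(diag(generalized_correlation(m)), c(1, 1))
})

test_that("occupancy contact map applies the inclusive 70% rule", {
  top <- bead_topology(2)
  mk <- function(seps) {
    traj_from_frames(top, lapply(seps, function(s) {
      rbind(c(0, 0, 0), c(s, 0, 0))
    }))
  }
  expect_true(occupancy_contact_map(mk(rep(0.3, 10)))[1, 2])
  # exactly 70% of frames in contact -> contact (inclusive)
  expect_true(occupancy_contact_map(mk(c(rep(0.3, 7), rep(0.8, 3))))[1, 2])
  expect_false(occupancy_contact_map(mk(c(rep(0.3, 6), rep(0.8, 4))))[1, 2])
  expect_false(occupancy_contact_map(mk(rep(0.55, 10)))[1, 2])
  cm <- occupancy_contact_map(mk(rep(0.3, 4)))
  expect_false(any(diag(cm)))
  expect_identical(cm, t(cm))
})

test_that("graph construction filters by contact and transforms weights", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.5
  r[1, 3] <- r[3, 1] <- 0.99   # high correlation but no contact
  r[2, 3] <- r[3, 2] <- 1.0
  dimnames(r) <- list(c("A", "B", "C"), c("A", "B", "C"))
  contacts <- matrix(c(FALSE, TRUE, FALSE,
                       TRUE, FALSE, TRUE,
                       FALSE, TRUE, FALSE), 3, 3)
  dimnames(contacts) <- dimnames(r)
  g <- build_graph(structure(r, class = c("correlation_matrix", "matrix")),
                   contacts)
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$edges$weight[g$edges$from == "A"], -log10(0.5),
               tolerance = 1e-12)
  expect_equal(g$edges$weight[g$edges$from == "B" & g$edges$to == "C"], 0)
  expect_false(any(g$edges$from == "A" & g$edges$to == "C"))
  expect_error(build_graph(structure(r, class = c("correlation_matrix",
                                                  "matrix")),
                           contacts[1:2, 1:2]),
               class = "mdbind_mismatch_error")
  # r = 0 pairs are omitted even when in contact
  r0 <- r; r0[1, 2] <- r0[2, 1] <- 0
  g0 <- build_graph(structure(r0, class = c("correlation_matrix", "matrix")),
                    contacts)
  expect_false(any(g0$edges$from == "A"))
})

test_that("Dijkstra finds minimal paths with deterministic tie-breaking", {
  # triangle: A-B 0.1, B-C 0.1, A-C 0.3 -> A->C via B
  W <- matrix(Inf, 3, 3); diag(W) <- 0
  W[1, 2] <- W[2, 1] <- 0.1
  W[2, 3] <- W[3, 2] <- 0.1
  W[1, 3] <- W[3, 1] <- 0.3
  g <- graph_from_weights(W)
  p <- shortest_paths_corr(g, 1, 3)
  expect_equal(p$path[[1]], c("N01", "N02", "N03"))
  expect_equal(p$total_weight, 0.2, tolerance = 1e-12)
  expect_equal(sum(p$edge_weights[[1]]), p$total_weight)  # additivity

  # source = target: single-node path, weight 0
  p0 <- shortest_paths_corr(g, 2, 2)
  expect_equal(p0$path[[1]], "N02")
  expect_equal(p0$total_weight, 0)

  # unreachable target reported as such
  W2 <- matrix(Inf, 3, 3); diag(W2) <- 0; W2[1, 2] <- W2[2, 1] <- 0.1
  p2 <- shortest_paths_corr(graph_from_weights(W2), 1, 3)
  expect_false(p2$reachable)

  # equal-weight tie broken lexicographically
  W3 <- matrix(Inf, 4, 4); diag(W3) <- 0
  W3[1, 2] <- W3[2, 1] <- 0.2; W3[2, 4] <- W3[4, 2] <- 0.2
  W3[1, 3] <- W3[3, 1] <- 0.2; W3[3, 4] <- W3[4, 3] <- 0.2
  p3 <- shortest_paths_corr(graph_from_weights(W3), 1, 4)
  expect_equal(p3$path[[1]], c("N01", "N02", "N04"))

  expect_error(shortest_paths_corr(g, "missing", 3),
               class = "mdbind_selection_error")
})

test_that("Dijkstra agrees with exhaustive enumeration and igraph", {
  set.seed(31)
  for (trial in 1:100) {
    n <- sample(3:8, 1)
    W <- random_weight_graph(n)
    g <- graph_from_weights(W)
    src <- 1; tgt <- n
    ours <- shortest_paths_corr(g, src, tgt)
    brute <- enumerate_shortest_path(g$weights, src, tgt)
    if (!ours$reachable) {
      expect_true(is.null(brute$path))
    } else {
      expect_equal(ours$total_weight, brute$weight, tolerance = 1e-9)
      expect_equal(match(ours$path[[1]], g$nodes), brute$path)
    }
  }
  # independent cross-check of distances against igraph on one graph
  set.seed(32)
  W <- random_weight_graph(8)
  g <- graph_from_weights(W)
  ig <- as_igraph(g)
  d_ig <- igraph::distances(ig, v = "N01")[1, ]
  ours <- shortest_paths_corr(g, 1, 1:8)
  got <- ifelse(ours$reachable, ours$total_weight, Inf)
  expect_equal(unname(got), unname(d_ig[ours$target]), tolerance = 1e-9)
})

test_that("raising a correlation never lengthens any shortest path", {
  set.seed(33)
  for (trial in 1:20) {
    W <- random_weight_graph(6)
    g <- graph_from_weights(W)
    base <- shortest_paths_corr(g, 1, 2:6)
    e <- which(is.finite(W) & upper.tri(W), arr.ind = TRUE)
    if (!nrow(e)) next
    pick <- e[sample(nrow(e), 1), ]
    W2 <- W
    W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- W[pick[1], pick[2]] / 2
    g2 <- graph_from_weights(W2)
    after <- shortest_paths_corr(g2, 1, 2:6)
    ok <- is.na(after$total_weight) |
      after$total_weight <= base$total_weight + 1e-12
    expect_true(all(ok, na.rm = TRUE))
  }
})

test_that("replica averaging and system differences are element-wise", {
  r1 <- structure(matrix(c(1, 0.4, 0.4, 1), 2, 2,
                         dimnames = list(c("A", "B"), c("A", "B"))),
                  class = c("correlation_matrix", "matrix"))
  r2 <- structure(matrix(c(1, 0.6, 0.6, 1), 2, 2,
                         dimnames = list(c("A", "B"), c("A", "B"))),
                  class = c("correlation_matrix", "matrix"))
  avg <- replica_average(list(r1, r2))
  expect_equal(avg[1, 2], 0.5)
  expect_equal(replica_average(list(r1, r1))[1, 2], 0.4)
  expect_equal(correlation_difference(avg, avg)[1, 2], 0)
  r3 <- r1; dimnames(r3) <- list(c("A", "C"), c("A", "C"))
  expect_error(replica_average(list(r1, r3)), class = "mdbind_mismatch_error")
  expect_error(correlation_difference(r1, r3), class = "mdbind_mismatch_error")
})
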