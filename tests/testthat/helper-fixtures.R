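# Shared fixtures and independent oracles used across the suite.

dipeptide_path <- function() {
  system.file("extdata", "ala_gly_dipeptide.pdb", package = "mdbind")
}

dipeptide_params_path <- function() {
  system.file("extdata", "ala_gly_params.tsv", package = "mdbind")
}

# two beads at a fixed separation along x, constant over n_frames
two_bead_traj <- function(sep, n_frames = 3, charge = c(1, -1), sigma = 0.3,
                          epsilon = 0) {
  top <- bead_topology(2, charge = charge, sigma = sigma, epsilon = epsilon)
  top <- set_group(top, "receptor", 1)
  top <- set_group(top, "ligand", 2)
  arr <- array(0, c(n_frames, 2, 3))
  arr[, 2, 1] <- sep
  list(topology = top,
       trajectory = as_trajectory(arr, top, times = seq_len(n_frames),
                                  discard_ns = 0))
}

# trajectory from an explicit per-frame coordinate list
traj_from_frames <- function(top, frames, discard_ns = 0) {
  arr <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  as_trajectory(arr, top, times = seq_along(frames), discard_ns = discard_ns)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
           2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
           2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3, byrow = TRUE)
}

# --- independent oracles ---------------------------------------------------

# exhaustive shortest-path enumeration over all simple paths; ties broken by
# the lexicographically smallest node sequence
enumerate_shortest_path <- function(W, src, tgt) {
  n <- nrow(W)
  best <- list(weight = Inf, path = NULL)
  consider <- function(path, w) {
    if (w < best$weight - 1e-12 ||
        (abs(w - best$weight) <= 1e-12 && !is.null(best$path) &&
         lex_less(path, best$path))) {
      best <<- list(weight = w, path = path)
    }
  }
  lex_less <- function(a, b) {
    k <- min(length(a), length(b))
    for (i in seq_len(k)) {
      if (a[i] != b[i]) return(a[i] < b[i])
    }
    length(a) < length(b)
  }
  dfs <- function(u, visited, path, w) {
    if (w > best$weight + 1e-12) return()
    if (u == tgt) { consider(path, w); return() }
    for (v in seq_len(n)) {
      if (!visited[v] && is.finite(W[u, v])) {
        visited[v] <- TRUE
        dfs(v, visited, c(path, v), w + W[u, v])
        visited[v] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n); visited[src] <- TRUE
  dfs(src, visited, src, 0)
  best
}

random_weight_graph <- function(n, p_edge = 0.5) {
  W <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) {
        w <- runif(1, 0.01, 1)
        W[i, j] <- W[j, i] <- w
      }
    }
  }
  diag(W) <- 0
  W
}

graph_from_weights <- function(W) {
  n <- nrow(W)
  corr <- 10^(-W)          # invert the -log10 transform
  corr[!is.finite(W)] <- 0
  diag(corr) <- 1
  contacts <- is.finite(W)
  diag(contacts) <- FALSE
  dimnames(corr) <- dimnames(contacts) <-
    list(sprintf("N%02d", seq_len(n)), sprintf("N%02d", seq_len(n)))
  build_graph(structure(corr, class = c("correlation_matrix", "matrix")),
              contacts)
}

# brute-force RMSD by grid search over Euler angles + local refinement
grid_search_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    Rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])),
                 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3]), 0, 0, 0, 1),
                  3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  obj <- function(a) sqrt(mean(rowSums((Pc %*% rot(a) - Qc)^2)))
  grid <- expand.grid(a1 = seq(0, 2 * pi, length.out = 13)[-13],
                      a2 = seq(0, pi, length.out = 7),
                      a3 = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  stats::optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}
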