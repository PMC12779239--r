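# Generalized-correlation networks: Kraskov kNN mutual information between
# 3-D residue displacement vectors, the r_MI transform, occupancy contact
# filtering, weighted-graph construction and Dijkstra shortest allosteric
# paths with deterministic tie-breaking.

#' Mutual-information matrix from a kNN (Kraskov) estimator
#'
#' Frames (optionally strided to mitigate autocorrelation) are globally
#' superposed to the ensemble mean so rigid-body motion does not masquerade
#' as correlation; each node's time series is its 3-D displacement about its
#' mean. Pairwise MI uses Kraskov algorithm 1 with the Chebyshev metric and
#' is clamped at >= 0.
#'
#' @param traj A trajectory ensemble.
#' @param selection Node atoms (default: name CA, i.e. one per residue).
#' @param k Number of neighbours (default 6).
#' @param stride Frame stride before estimation (default 10).
#' @param replica Replica index, or `NULL` to pool all replicas' analysis
#'   frames.
#' @param superpose Remove rigid-body motion first (default TRUE).
#' @return An n x n symmetric matrix of MI values in nats, with node labels
#'   as dimnames and attributes `k`, `stride`, `n_samples`.
#' @export
mi_matrix_knn <- function(traj, selection = NULL, k = 6, stride = 10,
                          replica = NULL, superpose = TRUE) {
  top <- traj$topology
  if (is.null(selection)) {
    selection <- which(top$atoms$name == "CA")
    if (!length(selection)) selection <- which(top$atoms$is_heavy)
  }
  reps <- if (is.null(replica)) seq_len(n_replicas(traj)) else replica
  stacks <- list()
  for (r in reps) {
    idx <- analysis_frames(traj, r, stride)
    for (i in idx) {
      stacks[[length(stacks) + 1L]] <-
        matrix(traj$replicas[[r]]$coords[i, selection, , drop = TRUE],
               length(selection))
    }
  }
  n <- length(stacks)
  if (n < 100) {
    abort_mdbind(sprintf("only %d frames after stride; need >= 100", n),
                 "mdbind_insufficient_data_error")
  }
  if (superpose && length(selection) >= 3) stacks <- superpose_to_mean(stacks)
  nn <- length(selection)
  # disp[frame, node*3]: displacement vectors about the node means
  flat <- t(vapply(stacks, as.vector, numeric(nn * 3)))
  flat <- sweep(flat, 2, colMeans(flat))
  mi <- cpp_ksg_mi_matrix(flat, nn, as.integer(k))
  labels <- top$residues$label[top$atoms$residue_index[selection]]
  dimnames(mi) <- list(labels, labels)
  attr(mi, "k") <- k; attr(mi, "stride") <- stride; attr(mi, "n_samples") <- n
  mi
}

#' Generalized correlation coefficient from mutual information
#'
#' r_MI = sqrt(1 - exp(-2 I / d)) element-wise, with d the dimensionality of
#' the node vectors (3 for Cartesian displacements); for a Gaussian pair
#' with per-dimension correlation rho this recovers |rho|. The diagonal is
#' forced to 1.
#'
#' @param mi MI matrix in nats (>= 0).
#' @param d Node dimensionality (default 3).
#' @return A `correlation_matrix`: matrix of r_MI in `[0, 1]` with
#'   attributes carried over.
#' @export
generalized_correlation <- function(mi, d = 3) {
  r <- sqrt(1 - exp(-2 * pmax(mi, 0) / d))
  diag(r) <- 1
  structure(r, class = c("correlation_matrix", "matrix"), d = d,
            k = attr(mi, "k"), stride = attr(mi, "stride"))
}

#' Occupancy-filtered residue contact map
#'
#' Residues are in contact when any pair of their heavy atoms is within
#' `cutoff` in at least a fraction `occupancy` of the analysis frames (both
#' thresholds inclusive).
#'
#' @param traj A trajectory ensemble.
#' @param cutoff Distance cutoff, nm (default 0.5).
#' @param occupancy Minimum occupancy fraction (default 0.70).
#' @param replica Replica index or `NULL` to pool replicas.
#' @return Symmetric logical matrix (FALSE diagonal) with residue labels.
#' @export
occupancy_contact_map <- function(traj, cutoff = 0.5, occupancy = 0.70,
                                  replica = NULL) {
  top <- traj$topology
  heavy <- which(top$atoms$is_heavy)
  res <- top$atoms$residue_index[heavy]
  nres <- nrow(top$residues)
  reps <- if (is.null(replica)) seq_len(n_replicas(traj)) else replica
  count <- matrix(0L, nres, nres)
  total <- 0L
  for (r in reps) {
    for (i in analysis_frames(traj, r)) {
      X <- matrix(traj$replicas[[r]]$coords[i, heavy, , drop = TRUE],
                  length(heavy))
      D <- pair_dist_matrix(X, X, traj$box)
      close <- D <= cutoff
      # residue-level any-pair aggregation
      hitmat <- matrix(FALSE, nres, nres)
      ij <- which(close, arr.ind = TRUE)
      hitmat[cbind(res[ij[, 1]], res[ij[, 2]])] <- TRUE
      count <- count + hitmat
      total <- total + 1L
    }
  }
  cm <- (count / total) >= occupancy
  diag(cm) <- FALSE
  cm <- cm | t(cm)
  dimnames(cm) <- list(top$residues$label, top$residues$label)
  cm
}

#' Build a contact-filtered correlation graph
#'
#' Edges exist only where the contact map is TRUE; edge weight is
#' -log10(r_MI), so weight 0 means perfect correlation. Pairs with r_MI <= 0
#' (infinite weight) are omitted.
#'
#' @param corr A [generalized_correlation()] matrix.
#' @param contacts Logical contact matrix of matching shape.
#' @param exclude_sequence_adjacent Drop edges between residues adjacent in
#'   sequence (default FALSE: they are retained).
#' @return A `correlation_graph`: list with `nodes` (labels), `edges`
#'   (tibble: `from`, `to`, `r_mi`, `weight`) and the weight matrix.
#' @export
build_graph <- function(corr, contacts, exclude_sequence_adjacent = FALSE) {
  if (!all(dim(corr) == dim(contacts))) {
    abort_mdbind("correlation and contact matrices differ in shape",
                 "mdbind_mismatch_error")
  }
  n <- nrow(corr)
  labels <- rownames(corr) %||% as.character(seq_len(n))
  W <- matrix(Inf, n, n)
  ij <- which(contacts & upper.tri(contacts), arr.ind = TRUE)
  if (exclude_sequence_adjacent && nrow(ij)) {
    ij <- ij[abs(ij[, 1] - ij[, 2]) != 1, , drop = FALSE]
  }
  keep <- corr[ij] > 0
  ij <- ij[keep, , drop = FALSE]
  w <- -log10(pmin(corr[ij], 1))
  W[ij] <- w; W[ij[, c(2, 1), drop = FALSE]] <- w
  edges <- tibble::tibble(from = labels[ij[, 1]], to = labels[ij[, 2]],
                          r_mi = corr[ij], weight = w)
  structure(list(nodes = labels, edges = edges, weights = W),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("<correlation_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a correlation graph to igraph
#' @param graph A `correlation_graph`.
#' @return An [igraph::graph_from_data_frame()] weighted undirected graph.
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges[, c("from", "to", "weight")],
                                directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

# O(n^2) Dijkstra over the dense weight matrix; returns distances from src
dijkstra_dist <- function(W, src) {
  n <- nrow(W)
  dist <- rep(Inf, n); dist[src] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    relax <- which(is.finite(W[u, ]) & !done)
    nd <- dist[u] + W[u, relax]
    upd <- nd < dist[relax]
    dist[relax[upd]] <- nd[upd]
  }
  dist
}

#' Shortest (preferential allosteric) paths in a correlation graph
#'
#' Dijkstra minimum-total-weight paths from a source residue to each target.
#' Among equal-weight shortest paths the lexicographically smallest node
#' sequence is returned (deterministic tie-breaking); unreachable targets
#' are reported with `reachable = FALSE`.
#'
#' @param graph A [build_graph()] result.
#' @param source Source node (label or index).
#' @param targets Target nodes (labels or indices).
#' @param tol Relative tolerance for tie detection.
#' @return An `allosteric_paths` tibble: `source`, `target`, `reachable`,
#'   `total_weight`, `n_edges`, and list-columns `path` (node labels) and
#'   `edge_weights`.
#' @export
shortest_paths_corr <- function(graph, source, targets, tol = 1e-9) {
  lab <- graph$nodes
  to_idx <- function(x) {
    if (is.character(x)) {
      i <- match(x, lab)
      if (anyNA(i)) {
        abort_mdbind(sprintf("unknown node '%s'", x[which(is.na(i))[1]]),
                     "mdbind_selection_error")
      }
      i
    } else as.integer(x)
  }
  src <- to_idx(source)
  if (src < 1 || src > length(lab)) {
    abort_mdbind("source is not a graph node", "mdbind_selection_error")
  }
  tgt <- to_idx(targets)
  W <- graph$weights
  rows <- purrr::map_dfr(tgt, function(t1) {
    d_t <- dijkstra_dist(W, t1)  # undirected: distance-to-target
    if (!is.finite(d_t[src])) {
      return(tibble::tibble(source = lab[src], target = lab[t1],
                            reachable = FALSE, total_weight = NA_real_,
                            n_edges = NA_integer_, path = list(character(0)),
                            edge_weights = list(numeric(0))))
    }
    # greedy lexicographic reconstruction along tight edges
    path <- src; u <- src
    guard <- 0L
    while (u != t1 && guard <= length(lab)^2) {
      nb <- which(is.finite(W[u, ]))
      tight <- nb[abs(W[u, nb] + d_t[nb] - d_t[u]) <=
                    tol * max(1, abs(d_t[u]))]
      tight <- setdiff(tight, path)  # zero-weight cycles cannot help
      if (!length(tight)) tight <- nb[which.min(W[u, nb] + d_t[nb])]
      u <- min(tight)
      path <- c(path, u)
      guard <- guard + 1L
    }
    ew <- W[cbind(path[-length(path)], path[-1])]
    tibble::tibble(source = lab[src], target = lab[t1], reachable = TRUE,
                   total_weight = sum(ew), n_edges = length(ew),
                   path = list(lab[path]), edge_weights = list(ew))
  })
  class(rows) <- c("allosteric_paths", class(rows))
  rows
}

#' @export
tidy.allosteric_paths <- function(x, ...) {
  tibble::as_tibble(x[, c("source", "target", "reachable", "total_weight",
                          "n_edges")])
}

#' Replica-averaged correlation matrix
#'
#' Element-wise mean of r_MI across replicas (identical node sets required).
#'
#' @param matrices List of [generalized_correlation()] matrices.
#' @return A `correlation_matrix` of the same shape.
#' @export
replica_average <- function(matrices) {
  if (!length(matrices)) abort_mdbind("no matrices", "mdbind_mismatch_error")
  dims <- lapply(matrices, dimnames)
  for (d in dims[-1]) {
    if (!identical(d, dims[[1]])) {
      abort_mdbind("replica matrices have mismatching node sets",
                   "mdbind_mismatch_error")
    }
  }
  avg <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  structure(avg, class = c("correlation_matrix", "matrix"),
            d = attr(matrices[[1]], "d"))
}

#' Correlation difference between two systems
#'
#' @param corr_1,corr_2 Replica-averaged `correlation_matrix` objects with
#'   identical node sets.
#' @return Matrix of element-wise differences mean(system1) - mean(system2).
#' @export
correlation_difference <- function(corr_1, corr_2) {
  if (!identical(dimnames(corr_1), dimnames(corr_2))) {
    abort_mdbind("systems have mismatching node sets", "mdbind_mismatch_error")
  }
  unclass(corr_1) - unclass(corr_2)
}

#' Per-replica generalized-correlation matrices, averaged
#'
#' Convenience wrapper mirroring the replica convention: estimate the MI
#' matrix separately for each replica, transform to r_MI, then average.
#'
#' @inheritParams mi_matrix_knn
#' @param d Node dimensionality for the transform.
#' @return List with `per_replica` (list of `correlation_matrix`) and
#'   `average`.
#' @export
correlation_pipeline <- function(traj, selection = NULL, k = 6, stride = 10,
                                 superpose = TRUE, d = 3) {
  per <- lapply(seq_len(n_replicas(traj)), function(r) {
    generalized_correlation(
      mi_matrix_knn(traj, selection, k = k, stride = stride, replica = r,
                    superpose = superpose), d = d)
  })
  list(per_replica = per, average = replica_average(per))
}

#' @export
autoplot.correlation_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("node_i", "node_j", "r_mi")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_i, y = .data$node_j,
                                   fill = .data$r_mi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r_MI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
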