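# Stability and flexibility metrics: RMSD after optimal (Kabsch)
# superposition, block-averaged RMSF, radius of gyration, hydrogen-bond
# counts, residue-pair distance series and contact occupancy.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `P` onto `Q` (rows = atoms).
#'
#' @param P,Q n x 3 coordinate matrices (nm).
#' @param weights Optional per-atom weights.
#' @return List with `rotation` (3 x 3, applied as `P %*% rotation`),
#'   `translation` (length 3), and `transform(X)` applying both.
#' @export
kabsch <- function(P, Q, weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(P)) else weights
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  A <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  translation <- cq - as.vector(cp %*% A)
  list(rotation = A, translation = translation,
       transform = function(X) sweep(X %*% A, 2, translation, `+`))
}

#' RMSD between two frames after optimal superposition
#'
#' Fits `frame` onto `reference` on the `fit` selection (Kabsch) and reports
#' the RMSD over the `measure` selection.
#'
#' @param frame,reference [frame] objects sharing an atom order.
#' @param fit Atom indices used for the superposition (>= 3, non-collinear).
#' @param measure Atom indices the RMSD is computed over (default: `fit`).
#' @return List `(rotation, translation, rmsd)`, RMSD in nm.
#' @export
superpose_rmsd <- function(frame, reference, fit, measure = fit) {
  P <- frame$coordinates[fit, , drop = FALSE]
  Q <- reference$coordinates[fit, , drop = FALSE]
  if (nrow(P) < 3) {
    abort_mdbind("fit selection needs at least 3 atoms", "mdbind_degenerate_fit_error")
  }
  Pc <- sweep(P, 2, colMeans(P))
  if (sum(svd(Pc)$d > 1e-10 * max(1, max(abs(Pc)))) < 2) {
    abort_mdbind("fit selection is collinear/degenerate", "mdbind_degenerate_fit_error")
  }
  k <- kabsch(P, Q)
  moved <- k$transform(frame$coordinates[measure, , drop = FALSE])
  ref <- reference$coordinates[measure, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((moved - ref)^2)))
  list(rotation = k$rotation, translation = k$translation, rmsd = rmsd)
}

#' RMSD time series against a reference frame
#'
#' @param traj A trajectory ensemble.
#' @param reference A [frame] (e.g. the crystallographic structure).
#' @param fit,measure Atom selections as in [superpose_rmsd()].
#' @param include_discard Include frames inside the discard window (the usual
#'   stability plot shows them).
#' @return Tibble with columns `replica`, `time_ps`, `rmsd_nm`.
#' @export
rmsd_series <- function(traj, reference, fit, measure = fit,
                        include_discard = TRUE) {
  out <- purrr::map_dfr(seq_len(n_replicas(traj)), function(r) {
    idx <- if (include_discard) {
      seq_len(dim(traj$replicas[[r]]$coords)[1])
    } else {
      analysis_frames(traj, r)
    }
    tibble::tibble(
      replica = r,
      time_ps = traj$replicas[[r]]$time[idx],
      rmsd_nm = vapply(idx, function(i) {
        superpose_rmsd(get_frame(traj, r, i), reference, fit, measure)$rmsd
      }, numeric(1))
    )
  })
  out
}

# Iteratively superpose a stack of frames (list of n x 3 matrices) to their
# mean structure; two iterations remove rigid-body drift.
superpose_to_mean <- function(stack, n_iter = 2) {
  ref <- stack[[1]]
  for (it in seq_len(n_iter)) {
    fitted <- lapply(stack, function(X) kabsch(X, ref)$transform(X))
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  lapply(stack, function(X) kabsch(X, ref)$transform(X))
}

#' Block-averaged root-mean-square fluctuations
#'
#' Within each time block the frames are iteratively superposed to the block
#' mean structure and the per-atom RMSF computed about it; the profile is the
#' mean over blocks, then over replicas (per-replica and per-block values are
#' retained).
#'
#' @param traj A trajectory ensemble (its discard window is honoured).
#' @param selection Atom indices the RMSF is computed on (e.g. backbone or
#'   C-alpha).
#' @param block_ns Block length in ns (default 100).
#' @param n_iter Superposition iterations per block.
#' @param superpose Fit frames to the block mean before measuring
#'   fluctuations (default TRUE). The fit necessarily absorbs the six
#'   rigid-body degrees of freedom, so for synthetic ensembles whose beads
#'   fluctuate about a fixed reference (no rigid-body drift) `FALSE`
#'   recovers the planted per-bead fluctuation exactly.
#' @return A `flexibility_profile`: list with `profile` (tibble: `atom`,
#'   `label`, `rmsf_nm`), `blocks` (per replica x block values) and
#'   `metadata`. Has [tidy()] and [autoplot()] methods.
#' @export
rmsf_blocked <- function(traj, selection, block_ns = 100, n_iter = 2,
                         superpose = TRUE) {
  block_ps <- block_ns * 1000
  labels <- traj$topology$residues$label[
    traj$topology$atoms$residue_index[selection]]
  blocks <- purrr::map_dfr(seq_len(n_replicas(traj)), function(r) {
    idx <- analysis_frames(traj, r)
    if (!length(idx)) {
      abort_mdbind("no analysis frames after discard", "mdbind_insufficient_data_error")
    }
    t_rel <- traj$replicas[[r]]$time[idx] - traj$discard_ns * 1000
    n_blocks <- floor(max(t_rel) / block_ps)
    if (n_blocks < 1) {
      abort_mdbind("analysis span shorter than one block",
                   "mdbind_insufficient_data_error")
    }
    bid <- ceiling(t_rel / block_ps)
    keep <- bid <= n_blocks
    purrr::map_dfr(seq_len(n_blocks), function(b) {
      sub <- idx[keep & bid == b]
      stack <- lapply(sub, function(i) {
        traj$replicas[[r]]$coords[i, selection, , drop = TRUE]
      })
      fitted <- if (superpose && length(selection) >= 3) {
        superpose_to_mean(stack, n_iter)
      } else stack
      mean_str <- Reduce(`+`, fitted) / length(fitted)
      msf <- Reduce(`+`, lapply(fitted, function(X) rowSums((X - mean_str)^2))) /
        length(fitted)
      tibble::tibble(replica = r, block = b, atom = selection,
                     label = labels, rmsf_nm = sqrt(msf))
    })
  })
  per_rep <- dplyr::summarise(
    dplyr::group_by(blocks, .data$replica, .data$atom, .data$label),
    rmsf_nm = mean(.data$rmsf_nm), .groups = "drop")
  profile <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$atom, .data$label),
    sd_rep = if (dplyr::n() > 1) stats::sd(.data$rmsf_nm) / sqrt(dplyr::n()) else NA_real_,
    rmsf_nm = mean(.data$rmsf_nm), .groups = "drop")
  structure(list(
    profile = profile[, c("atom", "label", "rmsf_nm", "sd_rep")],
    blocks = blocks,
    metadata = list(block_ns = block_ns, discard_ns = traj$discard_ns,
                    selection = selection, n_replicas = n_replicas(traj))
  ), class = "flexibility_profile")
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat(sprintf("<flexibility_profile> %d atoms, block %g ns, discard %g ns, %d replica(s)\n",
              nrow(x$profile), x$metadata$block_ns, x$metadata$discard_ns,
              x$metadata$n_replicas))
  cat(sprintf("  mean RMSF %.4f nm (range %.4f-%.4f)\n",
              mean(x$profile$rmsf_nm), min(x$profile$rmsf_nm),
              max(x$profile$rmsf_nm)))
  invisible(x)
}

#' @export
tidy.flexibility_profile <- function(x, ...) x$profile

#' @export
autoplot.flexibility_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$atom, y = .data$rmsf_nm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "atom index", y = "RMSF (nm)",
                  title = sprintf("Block-averaged RMSF (%g ns blocks)",
                                  object$metadata$block_ns)) +
    ggplot2::theme_minimal()
}

#' Mass-weighted radius of gyration
#'
#' @param frame A [frame].
#' @param topology The matching [topology] (masses are taken from it).
#' @param selection Atom indices (default: all atoms).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, topology, selection = seq_len(n_atoms(topology))) {
  m <- topology$atoms$mass[selection]
  if (!length(m) || anyNA(m) || sum(m) <= 0) {
    abort_mdbind("selection has zero/unknown total mass", "mdbind_format_error")
  }
  X <- frame$coordinates[selection, , drop = FALSE]
  com <- colSums(X * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(X, 2, com)^2)) / sum(m))
}

#' Radius-of-gyration time series
#' @inheritParams rmsd_series
#' @param selection Atom indices.
#' @return Tibble with `replica`, `time_ps`, `rg_nm`.
#' @export
rg_series <- function(traj, selection = seq_len(n_atoms(traj$topology)),
                      include_discard = TRUE) {
  purrr::map_dfr(seq_len(n_replicas(traj)), function(r) {
    idx <- if (include_discard) {
      seq_len(dim(traj$replicas[[r]]$coords)[1])
    } else {
      analysis_frames(traj, r)
    }
    tibble::tibble(
      replica = r, time_ps = traj$replicas[[r]]$time[idx],
      rg_nm = vapply(idx, function(i) {
        radius_of_gyration(get_frame(traj, r, i), traj$topology, selection)
      }, numeric(1)))
  })
}

#' Infer donor-hydrogen pairs from geometry
#'
#' Pairs each hydrogen with the nearest N/O/S atom within `bond_max` nm.
#'
#' @param topology A [topology].
#' @param frame Reference [frame] used for the bond geometry.
#' @param bond_max Maximum covalent D-H distance (nm).
#' @return Data frame with columns `donor`, `hydrogen` (atom indices).
#' @export
infer_donors <- function(topology, frame, bond_max = 0.115) {
  hyd <- which(toupper(topology$atoms$element) == "H")
  heavy <- which(toupper(topology$atoms$element) %in% c("N", "O", "S"))
  if (!length(hyd) || !length(heavy)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0)))
  }
  X <- frame$coordinates
  rows <- lapply(hyd, function(h) {
    d2 <- rowSums(sweep(X[heavy, , drop = FALSE], 2, X[h, ])^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) <= bond_max) data.frame(donor = heavy[j], hydrogen = h)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(donor = integer(0), hydrogen = integer(0)) else out
}

#' Count hydrogen bonds in a frame
#'
#' Geometric criterion (both boundaries inclusive): donor-acceptor distance
#' <= `d_max` and H-D...A angle (at the donor, between the D->H and D->A
#' vectors) <= `angle_max`. The defaults 0.35 nm / 30 degrees are the common
#' MD-analysis convention.
#'
#' @param frame A [frame].
#' @param topology The matching [topology].
#' @param donors Data frame with columns `donor`, `hydrogen` (atom indices);
#'   see [infer_donors()]. A donor with a missing hydrogen is a
#'   configuration error.
#' @param acceptors Atom indices of acceptor atoms.
#' @param d_max Donor-acceptor cutoff (nm).
#' @param angle_max Angular cutoff (degrees).
#' @return Integer bond count.
#' @export
count_hbonds <- function(frame, topology, donors, acceptors,
                         d_max = 0.35, angle_max = 30) {
  if (!nrow(donors)) return(0L)
  if (anyNA(donors$hydrogen) || anyNA(donors$donor)) {
    bad <- which(is.na(donors$hydrogen) | is.na(donors$donor))[1]
    abort_mdbind(sprintf("donor row %d lacks a bonded hydrogen", bad),
                 "mdbind_configuration_error")
  }
  X <- frame$coordinates
  count <- 0L
  for (k in seq_len(nrow(donors))) {
    d <- donors$donor[k]; h <- donors$hydrogen[k]
    acc <- setdiff(acceptors, c(d, h))
    if (!length(acc)) next
    da <- sweep(X[acc, , drop = FALSE], 2, X[d, ], `-`)
    dist <- sqrt(rowSums(da^2))
    ok <- dist <= d_max
    if (!any(ok)) next
    vh <- X[h, ] - X[d, ]
    cosang <- (da[ok, , drop = FALSE] %*% vh) /
      (dist[ok] * sqrt(sum(vh^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    count <- count + sum(ang <= angle_max)
  }
  count
}

#' Hydrogen-bond count time series
#' @inheritParams rmsd_series
#' @param donors,acceptors,d_max,angle_max See [count_hbonds()].
#' @return Tibble with `replica`, `time_ps`, `n_hbonds`.
#' @export
hbond_series <- function(traj, donors, acceptors, d_max = 0.35,
                         angle_max = 30, include_discard = TRUE) {
  purrr::map_dfr(seq_len(n_replicas(traj)), function(r) {
    idx <- if (include_discard) {
      seq_len(dim(traj$replicas[[r]]$coords)[1])
    } else {
      analysis_frames(traj, r)
    }
    tibble::tibble(
      replica = r, time_ps = traj$replicas[[r]]$time[idx],
      n_hbonds = vapply(idx, function(i) {
        count_hbonds(get_frame(traj, r, i), traj$topology, donors, acceptors,
                     d_max, angle_max)
      }, integer(1)))
  })
}

#' Residue-pair distance series and contact occupancy
#'
#' Per-frame distances between residue pairs, either the minimum heavy-atom
#' distance or the distance between two named atoms, with the occupancy
#' (fraction of analysis frames at or below `threshold`, averaged over
#' replicas).
#'
#' @param traj A trajectory ensemble.
#' @param pairs Data frame with columns `res_a`, `res_b` (residue indices);
#'   for `mode = "named"` also `atom_a`, `atom_b` (atom-name strings).
#' @param mode `"min-heavy"` (default) or `"named"`.
#' @param threshold Contact threshold in nm (inclusive).
#' @return A `distance_series`: list with `series` (tibble: `replica`,
#'   `time_ps`, `pair`, `distance_nm`) and `occupancy` (tibble: `pair`,
#'   `occupancy`, per-replica values nested). Has a [tidy()] method.
#' @export
residue_pair_distances <- function(traj, pairs, mode = c("min-heavy", "named"),
                                   threshold = 0.45) {
  mode <- match.arg(mode)
  top <- traj$topology
  atom_sets <- lapply(seq_len(nrow(pairs)), function(k) {
    ra <- pairs$res_a[k]; rb <- pairs$res_b[k]
    if (mode == "min-heavy") {
      a <- which(top$atoms$residue_index == ra & top$atoms$is_heavy)
      b <- which(top$atoms$residue_index == rb & top$atoms$is_heavy)
    } else {
      a <- which(top$atoms$residue_index == ra & top$atoms$name == pairs$atom_a[k])
      b <- which(top$atoms$residue_index == rb & top$atoms$name == pairs$atom_b[k])
      if (!length(a) || !length(b)) {
        abort_mdbind(sprintf("named atom missing for pair %d (%s/%s)",
                             k, pairs$atom_a[k], pairs$atom_b[k]),
                     "mdbind_format_error")
      }
    }
    if (!length(a) || !length(b)) {
      abort_mdbind(sprintf("pair %d references residues without heavy atoms", k),
                   "mdbind_format_error")
    }
    list(a = a, b = b,
         label = paste(top$residues$label[ra], top$residues$label[rb], sep = "--"))
  })
  series <- purrr::map_dfr(seq_len(n_replicas(traj)), function(r) {
    idx <- analysis_frames(traj, r)
    purrr::map_dfr(seq_along(atom_sets), function(k) {
      s <- atom_sets[[k]]
      d <- vapply(idx, function(i) {
        Xa <- traj$replicas[[r]]$coords[i, s$a, , drop = FALSE]
        Xb <- traj$replicas[[r]]$coords[i, s$b, , drop = FALSE]
        min_cross_dist(Xa[1, , , drop = TRUE], Xb[1, , , drop = TRUE],
                       length(s$a), length(s$b))
      }, numeric(1))
      tibble::tibble(replica = r, time_ps = traj$replicas[[r]]$time[idx],
                     pair = s$label, distance_nm = d)
    })
  })
  occ_rep <- dplyr::summarise(
    dplyr::group_by(series, .data$pair, .data$replica),
    occupancy = mean(.data$distance_nm <= threshold), .groups = "drop")
  occupancy <- dplyr::summarise(
    dplyr::group_by(occ_rep, .data$pair),
    occupancy = mean(.data$occupancy), .groups = "drop")
  structure(list(series = series, occupancy = occupancy,
                 per_replica = occ_rep, threshold = threshold),
            class = "distance_series")
}

# minimum distance between two coordinate sets given flattening quirks of
# single-atom subsets
min_cross_dist <- function(Xa, Xb, na, nb) {
  Xa <- matrix(Xa, nrow = na); Xb <- matrix(Xb, nrow = nb)
  min(sqrt(outer(rowSums(Xa^2), rowSums(Xb^2), `+`) - 2 * Xa %*% t(Xb)))
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %d pair(s), threshold %.3g nm\n",
              nrow(x$occupancy), x$threshold))
  print(x$occupancy)
  invisible(x)
}

#' @export
tidy.distance_series <- function(x, ...) x$occupancy

#' @export
autoplot.distance_series <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$distance_nm, colour = .data$pair)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "distance (nm)", y = "density") +
    ggplot2::theme_minimal()
}
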