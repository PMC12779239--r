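# Synthetic trajectory ensembles, toy complexes and nonequilibrium work sets
# with analytically known planted structure. Every generator is a pure
# function of its spec and seed; each emulates exactly the statistical or
# geometric property a downstream stage needs, not physical realism.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Bead-chain topology for synthetic systems
#'
#' One carbon-like bead per residue so residue-level and atom-level analyses
#' coincide on synthetic systems.
#'
#' @param n Number of beads/residues.
#' @param chain_id Chain label.
#' @param mass,charge,sigma,epsilon Per-bead parameters (recycled).
#' @param name Atom name given to each bead.
#' @return A [topology].
#' @export
bead_topology <- function(n, chain_id = "S", mass = 12.011, charge = 0,
                          sigma = 0.3, epsilon = 0.5, name = "CA") {
  topology(data.frame(
    name = rep(name, n), element = "C",
    residue_index = seq_len(n), residue_name = "BEA",
    chain_id = chain_id, author_resid = seq_len(n),
    mass = rep_len(mass, n), charge = rep_len(charge, n),
    lj_sigma = rep_len(sigma, n), lj_epsilon = rep_len(epsilon, n),
    stringsAsFactors = FALSE
  ))
}

# Sample n_frames x n_res values per dimension from N(0, D R D), optionally
# AR(1)-correlated in time, and add them to reference coordinates.
sample_displacements <- function(ref, sds, R, n_frames, ar1 = 0) {
  n <- nrow(ref)
  L <- tryCatch(chol(R), error = function(e) {
    abort_mdbind("requested correlation matrix is not positive definite",
                 "mdbind_spec_error")
  })
  arr <- array(NA_real_, c(n_frames, n, 3))
  for (d in 1:3) {
    Z <- matrix(rnorm(n_frames * n), n_frames, n) %*% L
    if (ar1 > 0) {
      for (t in 2:n_frames) {
        Z[t, ] <- ar1 * Z[t - 1, ] + sqrt(1 - ar1^2) * Z[t, ]
      }
    }
    arr[, , d] <- sweep(Z, 2, sds, `*`)
    arr[, , d] <- sweep(arr[, , d], 2, ref[, d], `+`)
  }
  arr
}

#' Gaussian trajectory ensemble with planted inter-residue correlations
#'
#' Frames are i.i.d. draws (optionally AR(1) in time) from a multivariate
#' normal around a bead-chain reference; each spatial dimension of a planted
#' residue pair has Pearson correlation `rho`.
#'
#' @param n_residues Number of beads.
#' @param n_frames Frames per replica.
#' @param seed RNG seed; fully determines the output.
#' @param sd Per-residue isotropic displacement sd (nm), recycled.
#' @param correlations Data frame with columns `i`, `j`, `rho` (|rho| < 1);
#'   planted per shared dimension. `NULL` for independent residues.
#' @param spacing Reference bead spacing along x (nm).
#' @param n_replicas Number of independent replicas.
#' @param ar1 Optional AR(1) time-correlation coefficient (0 = i.i.d.) for
#'   stress-testing block averaging.
#' @param dt_ps Frame spacing, ps.
#' @return A [as_trajectory()] ensemble (discard 0: synthetic frames are
#'   already equilibrium draws).
#' @export
gen_gaussian_ensemble <- function(n_residues, n_frames, seed, sd = 0.05,
                                  correlations = NULL, spacing = 0.4,
                                  n_replicas = 1, ar1 = 0, dt_ps = 1) {
  sds <- rep_len(sd, n_residues)
  R <- diag(n_residues)
  if (!is.null(correlations)) {
    if (any(abs(correlations$rho) >= 1)) {
      abort_mdbind("planted |rho| must be < 1", "mdbind_spec_error")
    }
    for (k in seq_len(nrow(correlations))) {
      i <- correlations$i[k]; j <- correlations$j[k]
      R[i, j] <- R[j, i] <- correlations$rho[k]
    }
  }
  ref <- cbind((seq_len(n_residues) - 1) * spacing, 0, 0)
  top <- bead_topology(n_residues)
  local_seed(seed, {
    reps <- lapply(seq_len(n_replicas), function(r) {
      sample_displacements(ref, sds, R, n_frames, ar1)
    })
    as_trajectory(reps, top, times = seq_len(n_frames) * dt_ps, discard_ns = 0)
  })
}

#' Harmonic-well ensemble with analytic covariance
#'
#' Each bead fluctuates independently and isotropically with per-dimension
#' variance kB*T/k_i, giving closed forms for RMSF (sqrt(3 kB T / k)) and for
#' the Schlitter entropy; the analytic covariance is attached as attribute
#' `analytic`.
#'
#' @param n_residues Number of beads.
#' @param force_constants Per-bead force constants k_i (kJ/mol/nm^2),
#'   recycled; all must be > 0.
#' @param temperature Temperature (K); must be > 0.
#' @param n_frames Frames per replica.
#' @param seed RNG seed.
#' @param n_replicas Number of replicas.
#' @param spacing Reference bead spacing (nm).
#' @param mass Bead mass (amu).
#' @param dt_ps Frame spacing, ps.
#' @return A trajectory ensemble with attribute `analytic` = list
#'   (`var_per_dim`, `force_constants`, `temperature`, `mass`).
#' @export
gen_harmonic_wells <- function(n_residues, force_constants, temperature = 310,
                               n_frames, seed, n_replicas = 1, spacing = 1.0,
                               mass = 12.011, dt_ps = 1) {
  k <- rep_len(force_constants, n_residues)
  if (any(k <= 0)) abort_mdbind("force constants must be > 0", "mdbind_spec_error")
  if (temperature <= 0) {
    abort_mdbind("temperature must be > 0 (zero variance is degenerate)",
                 "mdbind_spec_error")
  }
  var_dim <- phys_constants$kB * temperature / k
  ref <- cbind((seq_len(n_residues) - 1) * spacing, 0, 0)
  top <- bead_topology(n_residues, mass = mass)
  traj <- local_seed(seed, {
    reps <- lapply(seq_len(n_replicas), function(r) {
      sample_displacements(ref, sqrt(var_dim), diag(n_residues), n_frames)
    })
    as_trajectory(reps, top, times = seq_len(n_frames) * dt_ps, discard_ns = 0)
  })
  attr(traj, "analytic") <- list(var_per_dim = var_dim, force_constants = k,
                                 temperature = temperature, mass = mass)
  traj
}

#' Specification for a two-group toy complex
#'
#' Defines a receptor bead sheet and a ligand bead sheet facing it, with one
#' planted opposite-charge pair (a "salt bridge") bridging the interface, and
#' a mutant variant that differs from the parent in exactly the declared
#' bead. The default mutant moves the salt-bridge ligand bead closer to its
#' receptor partner, emulating an engineered variant with a tighter
#' interfacial contact.
#'
#' @param n_receptor,n_ligand Bead counts per group (arranged on square-ish
#'   grids 0.5 nm apart).
#' @param plane_gap z-distance between the two sheets (nm).
#' @param bridge_gap Parent salt-bridge bead separation (nm).
#' @param mutant_bridge_gap Mutant salt-bridge separation (nm).
#' @param bridge_charge Magnitude of the salt-bridge charges (e).
#' @param background_charge Magnitude of the alternating background charges.
#' @param sigma,epsilon Lennard-Jones parameters for every bead.
#' @param jitter_sd Thermal jitter sd per bead per dimension (nm).
#' @param n_frames Frames per replica.
#' @param n_replicas Number of replicas.
#' @param seed RNG seed.
#' @return A list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_receptor = 25, n_ligand = 25, plane_gap = 0.7,
                             bridge_gap = 0.55, mutant_bridge_gap = 0.35,
                             bridge_charge = 1, background_charge = 0.2,
                             sigma = 0.3, epsilon = 0.5, jitter_sd = 0.02,
                             n_frames = 100, n_replicas = 1, seed = 1) {
  grid <- function(n, z) {
    side <- ceiling(sqrt(n))
    g <- expand.grid(x = (seq_len(side) - 1) * 0.5, y = (seq_len(side) - 1) * 0.5)
    cbind(g$x[seq_len(n)], g$y[seq_len(n)], z)
  }
  rec <- grid(n_receptor, 0)
  lig <- grid(n_ligand, plane_gap)
  lig[1, 3] <- bridge_gap  # planted salt-bridge partner sits above receptor bead 1
  charges <- c(
    c(bridge_charge, rep_len(c(-1, 1) * background_charge, n_receptor - 1)),
    c(-bridge_charge, rep_len(c(1, -1) * background_charge, n_ligand - 1))
  )
  structure(list(
    positions = rbind(rec, lig),
    n_receptor = n_receptor, n_ligand = n_ligand,
    charges = charges, sigma = sigma, epsilon = epsilon,
    mutant = list(bead = n_receptor + 1L,
                  position = c(lig[1, 1], lig[1, 2], mutant_bridge_gap),
                  charge = NULL),
    bridge_pair = c(1L, n_receptor + 1L),
    jitter_sd = jitter_sd, n_frames = n_frames, n_replicas = n_replicas,
    seed = seed
  ), class = "toy_complex_spec")
}

#' Generate parent and mutant toy complexes
#'
#' Parent and mutant share topology shape and differ in exactly the declared
#' bead (position and/or charge). Interface distances are controllable
#' through the spec geometry.
#'
#' @param spec A [toy_complex_spec()].
#' @return A list with elements `parent` and `mutant`, each a list
#'   `(topology, trajectory)` where the topology carries groups `receptor`
#'   and `ligand`, plus `bridge_pair` (the planted contact's residue
#'   indices).
#' @export
gen_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  n <- spec$n_receptor + spec$n_ligand
  build <- function(positions, charges, seed) {
    if (min(dist(positions)) < 0.05) {
      abort_mdbind("overlapping beads (< 0.05 nm) give singular energies",
                   "mdbind_spec_error")
    }
    top <- bead_topology(n, mass = 12.011, charge = charges,
                         sigma = spec$sigma, epsilon = spec$epsilon)
    top$atoms$chain_id <- rep(c("R", "L"), c(spec$n_receptor, spec$n_ligand))
    top$residues$chain_id <- top$atoms$chain_id
    top$residues$label <- paste0(top$residues$chain_id, ":BEA",
                                 top$residues$author_resid)
    top <- set_group(top, "receptor", seq_len(spec$n_receptor))
    top <- set_group(top, "ligand", spec$n_receptor + seq_len(spec$n_ligand))
    traj <- local_seed(seed, {
      reps <- lapply(seq_len(spec$n_replicas), function(r) {
        sample_displacements(positions, rep(spec$jitter_sd, n), diag(n),
                             spec$n_frames)
      })
      as_trajectory(reps, top, times = seq_len(spec$n_frames) * 1,
                    discard_ns = 0)
    })
    list(topology = top, trajectory = traj)
  }
  mut_pos <- spec$positions
  mut_charges <- spec$charges
  if (!is.null(spec$mutant$position)) mut_pos[spec$mutant$bead, ] <- spec$mutant$position
  if (!is.null(spec$mutant$charge)) mut_charges[spec$mutant$bead] <- spec$mutant$charge
  list(
    parent = build(spec$positions, spec$charges, spec$seed),
    mutant = build(mut_pos, mut_charges, spec$seed + 1L),
    bridge_pair = spec$bridge_pair
  )
}

#' Ensemble with a planted allosteric path
#'
#' Plants both the contact geometry and the correlation structure that make
#' a chosen residue chain the preferential communication route. The path
#' residues are laid out collinearly at `spacing` nm so only consecutive
#' path residues are in contact; the remaining residues form a detour arc
#' from source to target (so an alternative, weakly correlated route always
#' exists). Path edges get per-dimension correlation `rho_on`; detour edges
#' `rho_off`; implied non-edge correlations follow the Markov (max-product)
#' closure of the planted edges, the strongest structure consistent with
#' positive definiteness.
#'
#' @param n_residues Total residues (path plus detour).
#' @param path Residue indices of the planted path (1-based; first = source,
#'   last = target), e.g. `c(1, 4, 7, 10)`.
#' @param rho_on Correlation planted on path edges (must be >= `rho_off`).
#' @param rho_off Correlation planted on detour edges.
#' @param n_frames Frames per replica.
#' @param seed RNG seed.
#' @param spacing Path bead spacing (nm); must stay below the 0.5 nm contact
#'   cutoff used downstream.
#' @param jitter_sd Displacement sd per dimension (nm); small relative to
#'   `spacing` so planted contacts hold in well over 70% of frames.
#' @param n_replicas Number of replicas.
#' @return List `(topology, trajectory, path, correlation)` where `path`
#'   repeats the planted residue chain and `correlation` is the planted
#'   per-dimension correlation matrix actually used.
#' @export
gen_planted_path <- function(n_residues = 10, path = c(1, 4, 7, 10),
                             rho_on = 0.9, rho_off = 0.1, n_frames = 5000,
                             seed = 1, spacing = 0.45, jitter_sd = 0.03,
                             n_replicas = 1) {
  if (rho_off > rho_on) {
    abort_mdbind("rho_off must not exceed rho_on", "mdbind_spec_error")
  }
  if (rho_on >= 1 || rho_off < 0) {
    abort_mdbind("correlations must satisfy 0 <= rho_off <= rho_on < 1",
                 "mdbind_spec_error")
  }
  if (any(path < 1 | path > n_residues) || anyDuplicated(path)) {
    abort_mdbind("path must be distinct residue indices", "mdbind_spec_error")
  }
  detour <- setdiff(seq_len(n_residues), path)

  # geometry: path along x; detour on a semicircular arc from source to target
  pos <- matrix(NA_real_, n_residues, 3)
  pos[path, ] <- cbind((seq_along(path) - 1) * spacing, 0, 0)
  src <- path[1]; tgt <- path[length(path)]
  if (length(detour)) {
    span <- pos[tgt, 1] - pos[src, 1]
    radius <- span / 2
    ang <- seq(pi, 0, length.out = length(detour) + 2)[-c(1, length(detour) + 2)]
    pos[detour, ] <- cbind(radius + radius * cos(ang), radius * sin(ang), 0)
    seg <- cbind(c(src, detour), c(detour, tgt))
    seg_len <- sqrt(rowSums((pos[seg[, 1], , drop = FALSE] -
                               pos[seg[, 2], , drop = FALSE])^2))
    # contact margin: pair-distance sd is ~sqrt(2)*jitter_sd along the bond
    # axis; one sd of headroom keeps occupancy comfortably above 70%
    if (any((0.5 - seg_len) / (sqrt(2) * jitter_sd) < 1)) {
      abort_mdbind("detour too sparse: planted contacts not geometrically realizable",
                   "mdbind_spec_error")
    }
    detour_edges <- seg
  } else {
    detour_edges <- matrix(integer(0), 0, 2)
  }
  if ((0.5 - spacing) / (sqrt(2) * jitter_sd) < 1) {
    abort_mdbind("path spacing incompatible with the 0.5 nm contact rule",
                 "mdbind_spec_error")
  }

  # planted edges -> full correlation matrix via max-product (Markov) closure
  path_edges <- cbind(path[-length(path)], path[-1])
  W <- matrix(Inf, n_residues, n_residues)
  diag(W) <- 0
  add_edges <- function(W, edges, rho) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      w <- if (rho > 0) -log(rho) else Inf
      W[i, j] <- W[j, i] <- min(W[i, j], w)
    }
    W
  }
  W <- add_edges(W, path_edges, rho_on)
  W <- add_edges(W, detour_edges, rho_off)
  for (k in seq_len(n_residues)) {  # Floyd-Warshall
    W <- pmin(W, outer(W[, k], W[k, ], `+`))
  }
  R <- exp(-W)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {  # PD repair; must not move planted entries
    vals <- pmax(ev$values, 1e-6)
    R2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R2 <- R2 / sqrt(outer(diag(R2), diag(R2)))
    if (max(abs(R2 - R)) > 0.02) {
      abort_mdbind("planted correlation structure is not positive definite",
                   "mdbind_spec_error")
    }
    R <- R2
  }

  top <- bead_topology(n_residues)
  traj <- local_seed(seed, {
    reps <- lapply(seq_len(n_replicas), function(r) {
      sample_displacements(pos, rep(jitter_sd, n_residues), R, n_frames)
    })
    as_trajectory(reps, top, times = seq_len(n_frames) * 1, discard_ns = 0)
  })
  list(topology = top, trajectory = traj, path = path, correlation = R)
}

#' Crooks-consistent Gaussian work sets
#'
#' Forward works are N(dG + beta sigma^2/2, sigma^2) and backward works
#' N(-dG + beta sigma^2/2, sigma^2) with beta = 1/(kB T), which satisfies
#' the Crooks fluctuation relation exactly in distribution (and hence the
#' Gaussian Jarzynski identity).
#'
#' @param delta_g Planted free-energy difference (kJ/mol).
#' @param sigma Work sd (kJ/mol), > 0.
#' @param temperature Temperature (K).
#' @param n_forward,n_backward Sample sizes (>= 2 each).
#' @param seed RNG seed.
#' @return A [work_set()] with the planted parameters attached as attribute
#'   `planted`.
#' @export
gen_work_sets <- function(delta_g, sigma, temperature = 310,
                          n_forward = 300, n_backward = 300, seed = 1) {
  if (sigma <= 0) abort_mdbind("sigma must be > 0", "mdbind_spec_error")
  if (n_forward < 2 || n_backward < 2) {
    abort_mdbind("need at least 2 works per direction", "mdbind_spec_error")
  }
  beta <- 1 / (phys_constants$kB * temperature)
  ws <- local_seed(seed, {
    fw <- rnorm(n_forward, delta_g + beta * sigma^2 / 2, sigma)
    bw <- rnorm(n_backward, -delta_g + beta * sigma^2 / 2, sigma)
    work_set(fw, bw, temperature)
  })
  attr(ws, "planted") <- list(delta_g = delta_g, sigma = sigma)
  ws
}
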