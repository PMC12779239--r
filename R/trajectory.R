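# Trajectory ensembles: one or more replicas of time-stamped coordinate
# frames tied to a topology, carrying the discard-equilibration convention
# (initial window excluded from all time averages; default 200 ns).

#' Construct a single coordinate frame
#'
#' @param coordinates Numeric matrix, n_atoms x 3, in nm.
#' @param time Time stamp in ps.
#' @param box Optional length-3 vector of box lengths (nm) for minimum-image
#'   distance computations.
#' @return An object of class `frame`.
#' @export
frame <- function(coordinates, time = 0, box = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) {
    abort_mdbind("frame coordinates must be an n x 3 matrix", "mdbind_format_error")
  }
  if (!all(is.finite(coordinates))) {
    abort_mdbind("frame coordinates must all be finite", "mdbind_format_error")
  }
  structure(list(coordinates = coordinates, time = time, box = box),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame> %d atoms, t = %g ps\n", nrow(x$coordinates), x$time))
  invisible(x)
}

#' Build a trajectory ensemble from coordinate arrays
#'
#' This is the array-based frame-format adapter: any reader of a binary
#' trajectory format (XTC, DCD, ...) only has to deliver, per replica, a
#' `n_frames x n_atoms x 3` array in nm plus a strictly increasing time
#' vector in ps, and the whole downstream stack applies unchanged.
#'
#' @param coords One array (`n_frames x n_atoms x 3`, nm) or a list of such
#'   arrays, one per replica.
#' @param topology The shared [topology].
#' @param times Numeric vector of frame times in ps (recycled across
#'   replicas), or a list of vectors, one per replica.
#' @param discard_ns Initial time window (ns) excluded from all averages.
#' @param box Optional box lengths (nm).
#' @return An object of class `trajectory_ensemble`.
#' @export
as_trajectory <- function(coords, topology, times = NULL, discard_ns = 200,
                          box = NULL) {
  if (!is.list(coords)) coords <- list(coords)
  if (!is.null(times) && !is.list(times)) times <- rep(list(times), length(coords))
  replicas <- lapply(seq_along(coords), function(r) {
    arr <- coords[[r]]
    if (length(dim(arr)) != 3 || dim(arr)[3] != 3) {
      abort_mdbind("each replica must be an n_frames x n_atoms x 3 array",
                   "mdbind_format_error")
    }
    if (dim(arr)[2] != n_atoms(topology)) {
      abort_mdbind(sprintf(
        "replica %d has %d atoms but the topology has %d", r, dim(arr)[2],
        n_atoms(topology)), "mdbind_mismatch_error")
    }
    tt <- if (is.null(times)) seq_len(dim(arr)[1]) * 1000 else times[[r]]
    if (length(tt) != dim(arr)[1]) {
      abort_mdbind("times length must match frame count", "mdbind_format_error")
    }
    if (any(diff(tt) <= 0)) {
      abort_mdbind("frame times must be strictly increasing", "mdbind_format_error")
    }
    list(coords = arr, time = as.numeric(tt))
  })
  structure(list(replicas = replicas, topology = topology,
                 discard_ns = discard_ns, box = box),
            class = "trajectory_ensemble")
}

#' Load a trajectory from a multi-model PDB file
#'
#' Each MODEL in the file becomes one frame; frame times are assigned as
#' `dt_ps` apart. Frames inside the discard window are kept in the object
#' (the original frame count is part of the record) but excluded from every
#' time-averaged analysis via [analysis_frames()].
#'
#' @param path Multi-model PDB path.
#' @param topology The [topology] the frames must match.
#' @param dt_ps Time spacing between models, ps (default 1000 ps = 1 ns).
#' @param discard_ns Equilibration window to exclude (ns; default 200).
#' @return A [as_trajectory()] ensemble with one replica.
#' @export
load_trajectory <- function(path, topology, dt_ps = 1000, discard_ns = 200) {
  validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  if (nat != n_atoms(topology)) {
    abort_mdbind(sprintf("trajectory has %d atoms but topology has %d",
                         nat, n_atoms(topology)), "mdbind_mismatch_error")
  }
  nf <- nrow(xyz)
  arr <- array(NA_real_, c(nf, nat, 3))
  for (i in seq_len(nf)) {
    arr[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
  }
  as_trajectory(arr, topology, times = seq_len(nf) * dt_ps,
                discard_ns = discard_ns)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(r) dim(r$coords)[1], integer(1))
  cat(sprintf("<trajectory_ensemble> %d replica(s), frames: %s; %d atoms; discard %g ns\n",
              length(x$replicas), paste(nf, collapse = "/"),
              n_atoms(x$topology), x$discard_ns))
  invisible(x)
}

#' Number of replicas in an ensemble
#' @param traj A [as_trajectory()] ensemble.
#' @return Integer.
#' @export
n_replicas <- function(traj) length(traj$replicas)

#' Indices of post-equilibration analysis frames
#'
#' Frames with time strictly greater than the discard window are used for
#' every time-averaged quantity.
#'
#' @param traj A trajectory ensemble.
#' @param replica Replica index.
#' @param stride Keep every `stride`-th analysis frame.
#' @return Integer frame indices into the replica's coordinate array.
#' @export
analysis_frames <- function(traj, replica = 1L, stride = 1L) {
  tt <- traj$replicas[[replica]]$time
  idx <- which(tt > traj$discard_ns * 1000)
  idx[seq(1, length(idx), by = stride)]
}

#' Extract one frame of one replica
#' @param traj A trajectory ensemble.
#' @param replica Replica index.
#' @param i Frame index.
#' @return A [frame].
#' @export
get_frame <- function(traj, replica = 1L, i = 1L) {
  rep <- traj$replicas[[replica]]
  frame(rep$coords[i, , , drop = TRUE], time = rep$time[i], box = traj$box)
}

# Apply a function over analysis frames of a replica: f(coords_matrix) -> value
map_analysis_frames <- function(traj, replica, f, stride = 1L) {
  idx <- analysis_frames(traj, replica, stride)
  if (!length(idx)) {
    abort_mdbind("no analysis frames after the discard window",
                 "mdbind_insufficient_data_error")
  }
  lapply(idx, function(i) f(traj$replicas[[replica]]$coords[i, , , drop = TRUE]))
}
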