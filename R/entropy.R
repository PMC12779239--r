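# Schlitter configurational entropy, the binding-entropy cycle, and
# work-based free-energy estimation (Bennett acceptance ratio and Crooks
# Gaussian intersection) with the thermodynamic-cycle combination.

# Schlitter prefactor: kB T e^2 / hbar^2 expressed per (amu nm^2), so that
# alpha * eigenvalue(M^{1/2} C M^{1/2}) is dimensionless.
schlitter_alpha <- function(temperature) {
  with(phys_constants,
       kB_SI * temperature * exp(2) / hbar_SI^2 * amu_kg * 1e-18)
}

#' Schlitter configurational entropy
#'
#' Quasi-harmonic upper bound S = (kB/2) ln det(1 + kB T e^2/hbar^2 *
#' M^{1/2} C M^{1/2}), computed through the eigenvalues of the mass-weighted
#' Cartesian covariance (analysis frames only, after superposition to the
#' mean structure so rigid-body motion carries no entropy).
#'
#' @param traj A trajectory ensemble.
#' @param selection Atom indices (default: name CA).
#' @param temperature Temperature, K.
#' @param superpose Superpose frames to the mean first (default TRUE).
#' @param mode `"per_replica"` (covariance per replica, entropies averaged;
#'   default) or `"pooled"` (single covariance over all replicas).
#' @return An `entropy_result`: list with `S` (kJ/mol/K), `minus_TS`
#'   (kJ/mol), `temperature`, `per_replica`, `diagnostics` (frame counts,
#'   eigenvalue range, a low-sampling flag). Deterministic given frames.
#' @export
schlitter_entropy <- function(traj, selection = NULL, temperature = 310,
                              superpose = TRUE, mode = c("per_replica", "pooled")) {
  mode <- match.arg(mode)
  top <- traj$topology
  if (is.null(selection)) {
    selection <- which(top$atoms$name == "CA")
    if (!length(selection)) selection <- seq_len(n_atoms(top))
  }
  m <- top$atoms$mass[selection]
  if (anyNA(m)) abort_mdbind("masses required", "mdbind_missing_parameter_error")
  alpha <- schlitter_alpha(temperature)
  sqm <- rep(sqrt(m), times = 3)  # column-major flattening: x..x, y..y, z..z

  entropy_of_stack <- function(stack) {
    if (superpose && length(selection) >= 3) stack <- superpose_to_mean(stack)
    flat <- t(vapply(stack, as.vector, numeric(length(selection) * 3)))
    C <- stats::cov(flat)
    A <- C * outer(sqm, sqm)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    tolr <- 1e-10 * max(abs(ev), 1e-300)
    if (min(ev) < -sqrt(tolr) * max(1, max(abs(ev)))) {
      abort_mdbind("covariance is not positive semi-definite beyond tolerance",
                   "mdbind_numerical_error")
    }
    ev <- pmax(ev, 0)
    list(S = 0.5 * phys_constants$kB * sum(log1p(alpha * ev)),
         ev_range = range(ev), n = nrow(flat))
  }

  get_stack <- function(r) {
    lapply(analysis_frames(traj, r), function(i) {
      matrix(traj$replicas[[r]]$coords[i, selection, , drop = TRUE],
             length(selection))
    })
  }
  if (mode == "pooled") {
    stack <- unlist(lapply(seq_len(n_replicas(traj)), get_stack),
                    recursive = FALSE)
    res <- list(entropy_of_stack(stack))
  } else {
    res <- lapply(seq_len(n_replicas(traj)), function(r) {
      entropy_of_stack(get_stack(r))
    })
  }
  Svals <- vapply(res, `[[`, numeric(1), "S")
  nmin <- min(vapply(res, `[[`, numeric(1), "n"))
  diag_ <- list(
    n_frames = vapply(res, `[[`, numeric(1), "n"),
    eigen_range = range(unlist(lapply(res, `[[`, "ev_range"))),
    low_sampling = nmin < 3 * length(selection)
  )
  if (diag_$low_sampling) {
    warning(sprintf("fewer than 3N effective samples (%d < %d); entropy may be underconverged",
                    nmin, 3 * length(selection)))
  }
  S <- mean(Svals)
  structure(list(S = S, minus_TS = -temperature * S, temperature = temperature,
                 selection = selection, per_replica = Svals,
                 diagnostics = diag_),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("<entropy_result> S = %.6g kJ/mol/K at %g K (-TS = %.4g kJ/mol)\n",
              x$S, x$temperature, x$minus_TS))
  invisible(x)
}

#' @export
tidy.entropy_result <- function(x, ...) {
  tibble::tibble(S = x$S, minus_TS = x$minus_TS, temperature = x$temperature,
                 n_replicas = length(x$per_replica))
}

#' Quantum harmonic-oscillator entropy of a harmonic-well ensemble
#'
#' Closed form for the QHO entropy at the same frequencies as a
#' [gen_harmonic_wells()] system; the Schlitter estimate upper-bounds it.
#'
#' @param force_constants Per-bead k (kJ/mol/nm^2).
#' @param mass Bead mass (amu).
#' @param temperature K.
#' @return Entropy in kJ/mol/K (3 degrees of freedom per bead).
#' @export
qho_entropy <- function(force_constants, mass, temperature) {
  omega <- 1e12 * sqrt(force_constants / mass)  # rad/s
  x <- phys_constants$hbar_SI * omega / (phys_constants$kB_SI * temperature)
  3 * phys_constants$kB * sum(x / (exp(x) - 1) - log1p(-exp(-x)))
}

#' Binding-entropy cycle
#'
#' Per system Delta S_b = S(complex) - sum S(parts); the comparison
#' quantity is -T * (Delta S_b,1 - Delta S_b,2), positive when system 1 pays
#' a larger entropic penalty on binding.
#'
#' @param s_complex_1,s_complex_2 Complex entropies (kJ/mol/K); numbers or
#'   `entropy_result`s.
#' @param s_parts_1,s_parts_2 Vectors of component entropies.
#' @param temperature K.
#' @return List with `delta_s_1`, `delta_s_2`, `minus_T_dd_S` (kJ/mol).
#' @export
entropy_cycle <- function(s_complex_1, s_parts_1, s_complex_2, s_parts_2,
                          temperature = 310) {
  val <- function(x) if (inherits(x, "entropy_result")) x$S else as.numeric(x)
  ds1 <- val(s_complex_1) - sum(vapply(as.list(s_parts_1), val, numeric(1)))
  ds2 <- val(s_complex_2) - sum(vapply(as.list(s_parts_2), val, numeric(1)))
  list(delta_s_1 = ds1, delta_s_2 = ds2,
       minus_T_dd_S = -temperature * (ds1 - ds2), temperature = temperature)
}

#' Direction-labelled nonequilibrium work values
#'
#' @param forward,backward Work values (kJ/mol) for the forward and backward
#'   transformations (at least 2 each for BAR).
#' @param temperature K.
#' @return A `work_set`.
#' @export
work_set <- function(forward, backward, temperature = 310) {
  structure(list(forward = as.numeric(forward),
                 backward = as.numeric(backward),
                 temperature = temperature), class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("<work_set> %d forward / %d backward works at %g K\n",
              length(x$forward), length(x$backward), x$temperature))
  cat(sprintf("  forward  mean %.3f sd %.3f kJ/mol\n", mean(x$forward),
              stats::sd(x$forward)))
  cat(sprintf("  backward mean %.3f sd %.3f kJ/mol\n", mean(x$backward),
              stats::sd(x$backward)))
  invisible(x)
}

#' Read / write two-column work tables
#'
#' Delimited text with header columns `direction` (`forward`/`backward`) and
#' `work` (kJ/mol).
#'
#' @param path File path.
#' @param temperature K (attached on read).
#' @return A [work_set()].
#' @export
read_work_table <- function(path, temperature = 310) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("direction", "work") %in% names(tab))) {
    abort_mdbind("work table needs columns direction, work", "mdbind_format_error")
  }
  work_set(tab$work[tab$direction == "forward"],
           tab$work[tab$direction == "backward"], temperature)
}

#' @rdname read_work_table
#' @param works A [work_set()].
#' @export
write_work_table <- function(path, works) {
  tab <- data.frame(
    direction = rep(c("forward", "backward"),
                    c(length(works$forward), length(works$backward))),
    work = c(works$forward, works$backward))
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

bar_root <- function(wf, wr, beta) {
  # Bennett self-consistent equation; wr are backward works mapped to the
  # forward frame (negated)
  nf <- length(wf); nb <- length(wr)
  lr <- log(nf / nb)
  g <- function(dg) {
    sum(1 / (1 + exp(lr + beta * (wf - dg)))) -
      sum(1 / (1 + exp(-lr - beta * (wr - dg))))
  }
  lo <- min(wf, wr) - 20 / beta
  hi <- max(wf, wr) + 20 / beta
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

cgi_intersection <- function(wf, wr) {
  mf <- mean(wf); mr <- mean(wr)
  sf <- stats::sd(wf); sr <- stats::sd(wr)
  if (!is.finite(sf) || !is.finite(sr) || abs(sf - sr) < 1e-9 * max(sf, sr, 1e-12)) {
    return((mf + mr) / 2)
  }
  a <- 1 / sr^2 - 1 / sf^2
  b <- 2 * (mf / sf^2 - mr / sr^2)
  cc <- mr^2 / sr^2 - mf^2 / sf^2 - 2 * log(sf / sr)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return((mf + mr) / 2)
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  roots[which.min(abs(roots - (mf + mr) / 2))]
}

#' Free-energy difference from forward/backward work distributions
#'
#' `method = "bar"` solves the Bennett acceptance-ratio self-consistent
#' equation on the forward works and the negated backward works;
#' `method = "cgi"` uses the Crooks Gaussian intersection (the crossing
#' point of the two fitted Gaussians, which reduces to the midpoint of the
#' means for equal variances). Uncertainty is a seeded bootstrap over both
#' directions.
#'
#' @param works A [work_set()], or forward works (then supply `backward`).
#' @param backward Backward works when `works` is a numeric vector.
#' @param temperature K (taken from the work set when given).
#' @param method `"bar"` (default) or `"cgi"`.
#' @param n_boot Bootstrap resamples for the uncertainty (default 100).
#' @param seed Bootstrap seed.
#' @return A `bar_result`: list with `delta_g`, `uncertainty` (kJ/mol),
#'   `method`, sample sizes, and `overlap_warning` when the two work
#'   distributions do not overlap.
#' @export
bar_delta_g <- function(works, backward = NULL, temperature = NULL,
                        method = c("bar", "cgi"), n_boot = 100, seed = 1) {
  method <- match.arg(method)
  if (inherits(works, "work_set")) {
    wf <- works$forward; wb <- works$backward
    temperature <- temperature %||% works$temperature
  } else {
    wf <- as.numeric(works); wb <- as.numeric(backward)
    temperature <- temperature %||% phys_constants$temperature_default
  }
  if (length(wf) < 2 || length(wb) < 2) {
    abort_mdbind("need at least 2 works per direction", "mdbind_insufficient_data_error")
  }
  beta <- 1 / (phys_constants$kB * temperature)
  wr <- -wb
  est <- function(f, r) {
    if (method == "bar") bar_root(f, r, beta) else cgi_intersection(f, r)
  }
  dg <- est(wf, wr)
  unc <- local_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      est(sample(wf, replace = TRUE), sample(wr, replace = TRUE))
    }, numeric(1))
    stats::sd(boots)
  })
  overlap <- !(min(wf) <= max(wr) && min(wr) <= max(wf))
  if (overlap) {
    warning("forward and backward work distributions do not overlap; estimate unreliable")
  }
  structure(list(delta_g = dg, uncertainty = unc, method = toupper(method),
                 n_forward = length(wf), n_backward = length(wb),
                 temperature = temperature, overlap_warning = overlap),
            class = "bar_result")
}

#' @export
print.bar_result <- function(x, ...) {
  cat(sprintf("<bar_result> %s: dG = %.3f +/- %.3f kJ/mol (n = %d/%d)\n",
              x$method, x$delta_g, x$uncertainty, x$n_forward, x$n_backward))
  if (x$overlap_warning) cat("  warning: work distributions do not overlap\n")
  invisible(x)
}

#' @export
tidy.bar_result <- function(x, ...) {
  tibble::tibble(method = x$method, delta_g = x$delta_g,
                 uncertainty = x$uncertainty, n_forward = x$n_forward,
                 n_backward = x$n_backward)
}

#' Thermodynamic-cycle combination of two alchemical legs
#'
#' The relative binding free energy of the two variants is the difference of
#' the mutation legs: DDG_b = dG_mut(complex) - dG_mut(isolated receptor),
#' with uncertainties propagated in quadrature.
#'
#' @param complex_leg,isolated_leg [bar_delta_g()] results (or lists with
#'   `delta_g` and `uncertainty`).
#' @return A `free_energy_cycle` with `ddg`, `uncertainty`, and both legs.
#' @export
ddg_cycle <- function(complex_leg, isolated_leg) {
  for (leg in list(complex_leg, isolated_leg)) {
    if (is.null(leg$delta_g)) {
      abort_mdbind("both cycle legs must provide delta_g", "mdbind_spec_error")
    }
  }
  u1 <- complex_leg$uncertainty %||% 0
  u2 <- isolated_leg$uncertainty %||% 0
  structure(list(ddg = complex_leg$delta_g - isolated_leg$delta_g,
                 uncertainty = sqrt(u1^2 + u2^2),
                 complex_leg = complex_leg, isolated_leg = isolated_leg),
            class = "free_energy_cycle")
}

#' @export
print.free_energy_cycle <- function(x, ...) {
  cat(sprintf("<free_energy_cycle> DDG_b = %.3f +/- %.3f kJ/mol\n",
              x$ddg, x$uncertainty))
  cat(sprintf("  complex leg  %.3f, isolated leg %.3f kJ/mol\n",
              x$complex_leg$delta_g, x$isolated_leg$delta_g))
  invisible(x)
}

#' @export
tidy.free_energy_cycle <- function(x, ...) {
  tibble::tibble(ddg = x$ddg, uncertainty = x$uncertainty,
                 delta_g_complex = x$complex_leg$delta_g,
                 delta_g_isolated = x$isolated_leg$delta_g)
}

#' @export
autoplot.work_set <- function(object, ...) {
  df <- tibble::tibble(
    direction = rep(c("forward", "-backward"),
                    c(length(object$forward), length(object$backward))),
    work = c(object$forward, -object$backward))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$work, fill = .data$direction)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::labs(x = "work (kJ/mol)", y = "count") +
    ggplot2::theme_minimal()
}
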