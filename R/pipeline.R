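# Orchestration: a single validated config drives flexibility -> energetics
# -> correlation/network -> entropy -> work-based DDG, with deterministic
# per-stage seeds, stage isolation, and delimited-table reports.

#' Build a validated pipeline configuration
#'
#' Systems are either synthetic (`type = "toy"`: parent/mutant pair from a
#' [toy_complex_spec()]) or file-based (`type = "files"` with `structure`,
#' `trajectory`, `parameters`, `groups`). All stage parameters carry the
#' standard defaults (200 ns discard, 100 ns RMSF blocks, 1.2 nm short-range
#' cutoff, 0.6 nm any-frame pair gate, 0.5 nm / 70% contact filter, 310 K).
#' The full config validates before any computation and round-trips through
#' YAML unchanged.
#'
#' @param systems Named list of system descriptions (see Details above).
#' @param stages Named list enabling/parameterizing stages: `flexibility`,
#'   `energetics`, `correlation`, `entropy`, `fep`. Set a stage to `NULL` to
#'   disable it, or to a list of parameter overrides.
#' @param toy_spec Arguments for [toy_complex_spec()] when any system has
#'   `type = "toy"`.
#' @param seed Master seed; per-stage seeds are derived by
#'   `(seed * 1009 + stage_rank) mod 2^31 - 1`.
#' @param output_dir Report directory.
#' @param temperature K.
#' @return A `run_config` list.
#' @export
run_config <- function(systems, stages = list(), toy_spec = list(), seed = 1,
                       output_dir = tempfile("mdbind_run_"),
                       temperature = 310) {
  defaults <- list(
    flexibility = list(block_ns = 100, selection = "name CA"),
    energetics = list(sr_cutoff = 1.2, pair_gate = 0.6, polar = TRUE,
                      pb_spacing = 0.0325, pb_padding = 1.0,
                      dense_stride = 1, sparse_stride = 10,
                      distance_threshold = 0.45,
                      group_a = "receptor", group_b = "ligand"),
    correlation = list(cutoff = 0.5, occupancy = 0.70, k = 6, stride = 10,
                       source = NULL, targets = NULL),
    entropy = list(mode = "per_replica"),
    fep = list(complex = NULL, isolated = NULL, method = "bar", n_boot = 100)
  )
  st <- list()
  for (nm in names(stages)) {
    if (!nm %in% names(defaults)) {
      abort_mdbind(sprintf("unknown stage '%s'", nm), "mdbind_config_error")
    }
    if (is.null(stages[[nm]])) next
    ov <- stages[[nm]]
    if (isTRUE(ov)) ov <- list()
    merged <- utils::modifyList(defaults[[nm]], ov)
    st[[nm]] <- merged[!vapply(merged, is.null, logical(1))]
  }
  cfg <- structure(list(systems = systems, stages = st, toy_spec = toy_spec,
                        seed = seed, output_dir = output_dir,
                        temperature = temperature),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!length(cfg$systems)) {
    abort_mdbind("config defines no systems", "mdbind_config_error")
  }
  for (nm in names(cfg$systems)) {
    s <- cfg$systems[[nm]]
    type <- s$type %||% "files"
    if (type == "toy") {
      if (is.null(s$role) || !s$role %in% c("parent", "mutant")) {
        abort_mdbind(sprintf("toy system '%s' needs role parent|mutant", nm),
                     "mdbind_config_error")
      }
    } else if (type == "files") {
      for (f in c("structure", "trajectory")) {
        if (is.null(s[[f]])) {
          abort_mdbind(sprintf("system '%s' lacks '%s'", nm, f),
                       "mdbind_config_error")
        }
      }
      if (!is.null(cfg$stages$energetics) && is.null(s$parameters)) {
        abort_mdbind(sprintf(
          "energetics enabled but system '%s' has no parameter table", nm),
          "mdbind_config_error")
      }
    } else {
      abort_mdbind(sprintf("unknown system type '%s'", type),
                   "mdbind_config_error")
    }
  }
  en <- cfg$stages$energetics
  if (!is.null(en) && en$sr_cutoff <= 0) {
    abort_mdbind("sr_cutoff must be > 0", "mdbind_config_error")
  }
  co <- cfg$stages$correlation
  if (!is.null(co) && (co$occupancy < 0 || co$occupancy > 1)) {
    abort_mdbind("contact occupancy must be in [0,1]", "mdbind_config_error")
  }
  invisible(cfg)
}

#' Read / write a pipeline config as YAML
#' @param path YAML file path.
#' @return A `run_config` (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(systems = y$systems, stages = y$stages %||% list(),
             toy_spec = y$toy_spec %||% list(), seed = y$seed %||% 1,
             output_dir = y$output_dir %||% tempfile("mdbind_run_"),
             temperature = y$temperature %||% 310)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(path, config) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_seed <- function(master, stage) {
  rank <- match(stage, c("generate", "flexibility", "energetics",
                         "correlation", "entropy", "fep"))
  as.integer((as.numeric(master) * 1009 + rank) %% (2^31 - 1))
}

resolve_systems <- function(cfg) {
  toy <- NULL
  out <- list()
  for (nm in names(cfg$systems)) {
    s <- cfg$systems[[nm]]
    if ((s$type %||% "files") == "toy") {
      if (is.null(toy)) {
        args <- cfg$toy_spec
        if (is.null(args$seed)) args$seed <- stage_seed(cfg$seed, "generate")
        toy <- gen_toy_complex(do.call(toy_complex_spec, args))
      }
      out[[nm]] <- c(toy[[s$role]], list(bridge_pair = toy$bridge_pair))
    } else {
      rs <- read_structure(s$structure)
      top <- rs$topology
      if (!is.null(s$parameters)) top <- read_atom_parameters(s$parameters, top)
      for (g in names(s$groups %||% list())) {
        top <- set_group(top, g, s$groups[[g]])
      }
      traj <- load_trajectory(s$trajectory, top, dt_ps = s$dt_ps %||% 1000,
                              discard_ns = s$discard_ns %||% 200)
      out[[nm]] <- list(topology = top, trajectory = traj)
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order for every system. A
#' failing stage is recorded in the failure manifest and does not prevent
#' other stages from completing; identical config + seed gives bit-identical
#' numeric results.
#'
#' @param config A [run_config()].
#' @return An `analysis_report`: per-system stage results, cross-system
#'   comparisons when exactly two systems are present, a failure manifest,
#'   and a provenance block (config echo, seed, package version).
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  systems <- resolve_systems(config)
  report <- list(systems = list(), comparison = list(), failures = list(),
                 provenance = list(
                   seed = config$seed,
                   temperature = config$temperature,
                   config = unclass(config),
                   package_version = as.character(utils::packageVersion("mdbind")),
                   timestamp = format(Sys.time(), tz = "UTC")))

  run_stage <- function(sysname, stage, expr) {
    tryCatch(expr, error = function(e) {
      report$failures[[length(report$failures) + 1L]] <<-
        list(system = sysname, stage = stage, message = conditionMessage(e))
      NULL
    })
  }

  for (nm in names(systems)) {
    sys <- systems[[nm]]
    traj <- sys$trajectory
    res <- list()

    if (!is.null(config$stages$flexibility)) {
      p <- config$stages$flexibility
      res$flexibility <- run_stage(nm, "flexibility", {
        sel <- select_atoms(traj$topology, p$selection)
        prof <- rmsf_blocked(traj, sel, block_ns = p$block_ns)
        ref <- get_frame(traj, 1, 1)
        list(rmsf = prof,
             rmsd = rmsd_series(traj, ref, sel),
             rg = rg_series(traj, sel))
      })
    }

    if (!is.null(config$stages$energetics)) {
      p <- config$stages$energetics
      res$energetics <- run_stage(nm, "energetics", {
        nb <- nonbonded_params(cutoff = p$sr_cutoff)
        pb <- if (isTRUE(p$polar)) {
          pb_settings(spacing = p$pb_spacing, padding = p$pb_padding,
                      temperature = config$temperature)
        } else NULL
        summ <- mmpbsa_summary(traj, p$group_a, p$group_b, params = nb,
                               pb = pb, dense_stride = p$dense_stride,
                               sparse_stride = p$sparse_stride)
        gates <- anyframe_contact_pairs(traj, p$group_a, p$group_b,
                                        cutoff = p$pair_gate)
        pet <- pair_energy_series(traj, gates, params = nb)
        dist <- if (!is.null(sys$bridge_pair)) {
          residue_pair_distances(
            traj, data.frame(res_a = sys$bridge_pair[1],
                             res_b = sys$bridge_pair[2]),
            threshold = p$distance_threshold)
        }
        list(summary = summ, gated_pairs = gates, pair_energies = pet,
             distances = dist)
      })
    }

    if (!is.null(config$stages$correlation)) {
      p <- config$stages$correlation
      res$correlation <- run_stage(nm, "correlation", {
        cp <- correlation_pipeline(traj, k = p$k, stride = p$stride)
        cm <- occupancy_contact_map(traj, cutoff = p$cutoff,
                                    occupancy = p$occupancy)
        gr <- build_graph(cp$average, cm)
        paths <- if (!is.null(p$source) && length(p$targets)) {
          shortest_paths_corr(gr, p$source, p$targets)
        }
        list(correlation = cp$average, contacts = cm, graph = gr,
             paths = paths)
      })
    }

    if (!is.null(config$stages$entropy)) {
      p <- config$stages$entropy
      res$entropy <- run_stage(nm, "entropy", {
        schlitter_entropy(traj, temperature = config$temperature,
                          mode = p$mode)
      })
    }
    report$systems[[nm]] <- res
  }

  if (!is.null(config$stages$fep)) {
    p <- config$stages$fep
    report$fep <- run_stage("(cycle)", "fep", {
      leg <- function(spec, which_leg) {
        if (is.null(spec)) {
          abort_mdbind(sprintf("fep stage lacks the %s leg", which_leg),
                       "mdbind_config_error")
        }
        ws <- if (!is.null(spec$file)) {
          read_work_table(spec$file, config$temperature)
        } else {
          gen_work_sets(spec$delta_g, spec$sigma,
                        temperature = config$temperature,
                        n_forward = spec$n %||% 300,
                        n_backward = spec$n %||% 300,
                        seed = stage_seed(config$seed, "fep") +
                          (which_leg == "isolated"))
        }
        bar_delta_g(ws, method = p$method, n_boot = p$n_boot,
                    seed = stage_seed(config$seed, "fep"))
      }
      ddg_cycle(leg(p$complex, "complex"), leg(p$isolated, "isolated"))
    })
  }

  # two-system comparison mirroring the parent/engineered logic
  if (length(report$systems) == 2 && !is.null(config$stages$energetics)) {
    nms <- names(report$systems)
    e1 <- report$systems[[1]]$energetics
    e2 <- report$systems[[2]]$energetics
    if (!is.null(e1) && !is.null(e2)) {
      s1 <- e1$summary$summary; s2 <- e2$summary$summary
      cmp <- tibble::tibble(term = s1$term, sys1 = s1$mean, sys2 = s2$mean,
                            difference = s2$mean - s1$mean)
      names(cmp)[2:3] <- nms
      occ <- NULL
      if (!is.null(e1$distances) && !is.null(e2$distances)) {
        occ <- tibble::tibble(pair = e1$distances$occupancy$pair,
                              sys1 = e1$distances$occupancy$occupancy,
                              sys2 = e2$distances$occupancy$occupancy)
        names(occ)[2:3] <- nms
      }
      report$comparison <- list(energy_terms = cmp, bridge_occupancy = occ)
    }
  }
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d system(s): %s\n", length(x$systems),
              paste(names(x$systems), collapse = ", ")))
  for (nm in names(x$systems)) {
    cat(sprintf("  %s: stages %s\n", nm,
                paste(names(x$systems[[nm]]), collapse = ", ")))
  }
  if (length(x$failures)) {
    cat(sprintf("  %d stage failure(s); see $failures\n", length(x$failures)))
  }
  if (length(x$comparison)) {
    cat("  comparison:\n")
    print(x$comparison$energy_terms)
  }
  invisible(x)
}

#' Write an analysis report as delimited tables plus a text summary
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written files, invisibly.
#' @export
write_report <- function(report, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    abort_mdbind(sprintf("cannot write to '%s'", dir), "mdbind_io_error")
  }
  files <- character(0)
  put <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
  }
  lines <- c("mdbind analysis report",
             sprintf("seed: %s", report$provenance$seed),
             sprintf("generated: %s UTC", report$provenance$timestamp), "")
  for (nm in names(report$systems)) {
    res <- report$systems[[nm]]
    if (!is.null(res$flexibility)) {
      put(res$flexibility$rmsf$profile, sprintf("%s_rmsf.tsv", nm))
      put(res$flexibility$rmsd, sprintf("%s_rmsd.tsv", nm))
    }
    if (!is.null(res$energetics)) {
      put(res$energetics$summary$summary, sprintf("%s_energy.tsv", nm))
      put(tibble::as_tibble(res$energetics$pair_energies),
          sprintf("%s_pair_energies.tsv", nm))
      if (!is.null(res$energetics$distances)) {
        put(res$energetics$distances$occupancy, sprintf("%s_occupancy.tsv", nm))
      }
      s <- res$energetics$summary$summary
      lines <- c(lines, sprintf("[%s] energy terms (kJ/mol):", nm),
                 sprintf("  %-14s %10.3f (%s)", s$term, s$mean,
                         ifelse(is.na(s$sigma_mu), "-",
                                sprintf("%.3f", s$sigma_mu))), "")
    } else {
      lines <- c(lines, sprintf("[%s] energetics section omitted", nm), "")
    }
    if (!is.null(res$correlation)) {
      put(res$correlation$graph$edges, sprintf("%s_graph_edges.tsv", nm))
      cm <- res$correlation$correlation
      f <- file.path(dir, sprintf("%s_correlation.tsv", nm))
      utils::write.table(as.data.frame(unclass(cm)), f, sep = "\t",
                         quote = FALSE)
      files <- c(files, f)
      if (!is.null(res$correlation$paths)) {
        pt <- res$correlation$paths
        put(tibble::tibble(
          source = pt$source, target = pt$target,
          total_weight = pt$total_weight,
          path = vapply(pt$path, paste, character(1), collapse = " -> "),
          edge_weights = vapply(pt$edge_weights, function(w) {
            paste(sprintf("%.4f", w), collapse = ",")
          }, character(1))), sprintf("%s_paths.tsv", nm))
      }
    }
    if (!is.null(res$entropy)) {
      lines <- c(lines, sprintf("[%s] Schlitter S = %.6g kJ/mol/K (-TS = %.4g kJ/mol)",
                                nm, res$entropy$S, res$entropy$minus_TS), "")
    }
  }
  if (!is.null(report$fep)) {
    lines <- c(lines,
               sprintf("DDG_b = %.3f +/- %.3f kJ/mol (legs: complex %.3f, isolated %.3f)",
                       report$fep$ddg, report$fep$uncertainty,
                       report$fep$complex_leg$delta_g,
                       report$fep$isolated_leg$delta_g), "")
  }
  if (length(report$comparison)) {
    put(report$comparison$energy_terms, "comparison_energy.tsv")
    if (!is.null(report$comparison$bridge_occupancy)) {
      put(report$comparison$bridge_occupancy, "comparison_occupancy.tsv")
    }
  }
  if (length(report$failures)) {
    put(purrr::map_dfr(report$failures, tibble::as_tibble), "failures.tsv")
    lines <- c(lines, sprintf("%d stage failure(s) recorded in failures.tsv",
                              length(report$failures)))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(c(files, file.path(dir, "summary.txt")))
}
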