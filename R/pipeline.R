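#' Pipeline configuration
#'
#' A nested list controlling an end-to-end run. Exactly one input source
#' must be chosen: the synthetic generator (`generator = list(...)`,
#' [generator_config()] fields) or real trajectories
#' (`inputs = list(topology = <pdb>, trajectories = list(STA = <file>, ...))`).
#' Other sections: `roles` (path to a YAML role map, optional),
#' `fingerprint` ([fingerprint_thresholds()] fields), `modes`
#' (`n_modes`, `n_perm`), `cavity` (`spacing`, `probe`, `min_blocked`,
#' `min_volume`, `seed_radius`, `open_threshold`, `stride`, `states`),
#' `bfactor` (`n_segments`), `report` (`plots` logical, `plot_format`).
#'
#' @param ... overrides merged over the defaults, as named nested lists.
#' @return a `kd_pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    generator = NULL,
    inputs = NULL,
    roles = NULL,
    fingerprint = list(),
    bfactor = list(n_segments = 10),
    modes = list(n_modes = 10, n_perm = 0),
    cavity = list(spacing = 1.0, probe = 1.4, min_blocked = 6,
                  min_volume = 27, seed_radius = 5.0, open_threshold = 200,
                  stride = 10, states = NULL),
    report = list(plots = FALSE, plot_format = "pdf"),
    seed = 1
  )
  cfg <- modifyList(defaults, list(...), keep.null = TRUE)
  structure(cfg, class = "kd_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with one section per module.
#' @return a `kd_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Print the default pipeline configuration as YAML
#'
#' @return the YAML string, invisibly; also printed.
#' @export
default_config_yaml <- function() {
  cfg <- unclass(pipeline_config(generator = list(n_frames = 1000)))
  txt <- yaml::as.yaml(cfg)
  cat(txt)
  invisible(txt)
}

validate_pipeline_config <- function(config) {
  has_gen <- !is.null(config$generator)
  has_real <- !is.null(config$inputs)
  if (has_gen == has_real) {
    abort("pipeline config must choose exactly one of 'generator' or 'inputs'")
  }
  if (has_real) {
    paths <- c(config$inputs$topology, unlist(config$inputs$trajectories))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      abort(paste0("input path(s) do not exist: ", paste(missing, collapse = ", ")))
    }
  }
  if (!is.null(config$roles) && !file.exists(config$roles)) {
    abort(paste0("role map does not exist: ", config$roles))
  }
  invisible(config)
}

pipeline_inputs <- function(config) {
  if (!is.null(config$generator)) {
    gen <- do.call(generator_config,
                   modifyList(config$generator, list(seed = config$seed)))
    panel <- simulate_panel(gen)
    roles <- if (!is.null(config$roles)) read_roles(config$roles) else panel$roles
    list(trajectories = panel$trajectories, topology = panel$topology,
         roles = roles, generator = gen)
  } else {
    st <- read_structure(config$inputs$topology)
    roles <- if (!is.null(config$roles)) read_roles(config$roles) else residue_roles()
    trajs <- list()
    for (state in names(config$inputs$trajectories)) {
      trajs[[state]] <- read_trajectory(config$inputs$trajectories[[state]],
                                        st$topology, state = state)
    }
    list(trajectories = trajs, topology = st$topology, roles = roles,
         generator = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' simulate/load -> descriptor panels -> fingerprints -> B-factor profiles
#' -> concatenated collective modes with per-state statistics -> pocket
#' tracking -> report. All stage outputs are written under `out_dir` with
#' deterministic file names; rerunning with an identical config and seed
#' reproduces generator-path outputs byte-identically.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return a `kd_report` list (also serialized to `report.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  inp <- with_stage("inputs", pipeline_inputs(config))
  topo <- inp$topology
  roles <- inp$roles
  states <- names(inp$trajectories)
  say("inputs", "%d states: %s (seed %d)", length(states),
      paste(states, collapse = ", "), config$seed)

  ca <- select_atoms(topo, "name CA")
  thresholds <- do.call(fingerprint_thresholds, config$fingerprint)

  fingerprints <- list()
  bfactors <- list()
  descriptor_summary <- list()
  for (state in states) {
    tr <- inp$trajectories[[state]]
    panel <- with_stage("descriptors", descriptor_panel(tr, topo, roles))
    write_series_csv(panel, file.path(out_dir, paste0("descriptors_", state, ".csv")))
    fp <- with_stage("fingerprint", fingerprint_trajectory(panel, thresholds))
    write_fingerprint(fp,
                      json_path = file.path(out_dir, paste0("fingerprint_", state, ".json")),
                      csv_path = file.path(out_dir, paste0("states_", state, ".csv")))
    fingerprints[[state]] <- fp
    bf <- with_stage("bfactor",
                     bfactor_profile(tr, topo, fit_sel = ca,
                                     n_segments = config$bfactor$n_segments))
    readr::write_csv(as_tibble(bf), file.path(out_dir, paste0("bfactor_", state, ".csv")))
    bfactors[[state]] <- bf
    descriptor_summary[[state]] <- panel |>
      dplyr::group_by(.data$name) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       .groups = "drop") |>
      dplyr::mutate(state = state, .before = 1)
    say("descriptors", "%s: %d frames", state, n_frames(tr))
  }
  descriptor_summary <- dplyr::bind_rows(descriptor_summary)
  readr::write_csv(descriptor_summary, file.path(out_dir, "descriptor_summary.csv"))

  aligned <- with_stage("modes", concat_align(inp$trajectories, topo, ca))
  n_modes <- min(config$modes$n_modes, nrow(aligned$xyz) - 1, ncol(aligned$xyz))
  modes <- with_stage("modes", compute_modes(aligned, n_modes = n_modes))
  stats <- with_stage("modes", state_amplitude_stats(modes))
  write_modeset(modes, out_dir)
  readr::write_csv(stats$by_state, file.path(out_dir, "mode_state_stats.csv"))
  readr::write_csv(stats$by_mode, file.path(out_dir, "mode_scores.csv"))
  perm <- NULL
  if (config$modes$n_perm > 0) {
    perm <- with_stage("modes",
                       mode_permutation_test(modes, n_perm = config$modes$n_perm,
                                             seed = config$seed))
    readr::write_csv(perm, file.path(out_dir, "mode_permutation.csv"))
  }
  say("modes", "%d modes over %d frames; top score %.1f",
      n_modes, nrow(modes$projections), max(stats$by_mode$score))

  cavity_states <- config$cavity$states %||% states
  pockets <- list()
  for (state in intersect(cavity_states, states)) {
    pt <- with_stage("cavity", track_pocket(
      inp$trajectories[[state]], topo, roles,
      seed_radius = config$cavity$seed_radius,
      open_threshold = config$cavity$open_threshold,
      spacing = config$cavity$spacing, probe = config$cavity$probe,
      min_blocked = config$cavity$min_blocked,
      min_volume = config$cavity$min_volume,
      stride = config$cavity$stride))
    readr::write_csv(tibble(time_ns = pt$time_ns, volume_A3 = pt$volume_A3,
                            open_bool = pt$open),
                     file.path(out_dir, paste0("pocket_", state, ".csv")))
    pockets[[state]] <- pt
    say("cavity", "%s: max %.0f A^3, open fraction %.2f", state,
        attr(pt, "max_volume"), attr(pt, "open_fraction"))
  }

  report <- structure(list(
    states = states,
    fingerprints = lapply(fingerprints, function(f) f$summary),
    bfactor_means = lapply(bfactors, function(b) mean(b$bfactor)),
    descriptor_summary = descriptor_summary,
    mode_stats = list(by_mode = stats$by_mode, top_mode = stats$by_mode$mode[
      which.min(stats$by_mode$rank)],
      eigenvalues = modes$eigenvalues[seq_len(n_modes)],
      permutation = perm),
    pockets = lapply(pockets, function(p) list(
      max_volume_A3 = attr(p, "max_volume"),
      argmax_frame = attr(p, "argmax_frame"),
      open_fraction = attr(p, "open_fraction"))),
    provenance = list(seed = config$seed,
                      config_hash = rlang::hash(unclass(config)),
                      package_version = as.character(utils::packageVersion("kindyn")))
  ), class = "kd_report")
  write_report(report, out_dir, config = config,
               objects = list(fingerprints = fingerprints, bfactors = bfactors,
                              stats = stats, pockets = pockets))
  report
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Write a pipeline report
#'
#' Produces `report.json`, a human-readable `summary.txt`, and (when
#' enabled in the config) plot files for the descriptor traces, B-factor
#' profiles, mode amplitudes and pocket volume series.
#'
#' @param report a `kd_report` from [run_pipeline()].
#' @param out_dir output directory.
#' @param config the pipeline config (controls plotting).
#' @param objects internal: the full result objects for plotting.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, config = pipeline_config(generator = list()),
                         objects = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con), add = TRUE)
  w <- function(...) writeLines(sprintf(...), con)
  w("kinase-domain trajectory analysis report")
  w("states (input order): %s", paste(report$states, collapse = ", "))
  for (s in report$states) {
    fp <- report$fingerprints[[s]]
    w("%-6s DFG %-11s (occ %.2f)  alphaC %-12s bridge %.2f  mean B %.1f A^2",
      s, fp$dominant_dfg, max(unlist(fp$dfg_occupancy)), fp$dominant_alphaC,
      fp$saltbridge_occupancy, report$bfactor_means[[s]])
  }
  if (!is.null(report$mode_stats)) {
    w("top discriminative mode: %d", report$mode_stats$top_mode)
  }
  for (s in names(report$pockets)) {
    p <- report$pockets[[s]]
    w("pocket %-6s max %.0f A^3 (frame %d), open fraction %.2f",
      s, p$max_volume_A3, p$argmax_frame, p$open_fraction)
  }
  w("seed %d  config %s  kindyn %s", report$provenance$seed,
    report$provenance$config_hash, report$provenance$package_version)

  if (isTRUE(config$report$plots) && !is.null(objects)) {
    fmt <- config$report$plot_format %||% "pdf"
    save_plot <- function(p, nm) {
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".", fmt)), p,
                      width = 8, height = 5)
    }
    save_plot(plot_bfactors(objects$bfactors), "bfactors")
    save_plot(autoplot(objects$stats), "mode_amplitudes")
    if (length(objects$pockets) > 0) {
      save_plot(plot_pockets(objects$pockets), "pocket_volumes")
    }
  }
  invisible(out_dir)
}

report_to_list <- function(report) {
  list(states = report$states,
       fingerprints = report$fingerprints,
       bfactor_means = report$bfactor_means,
       descriptor_summary = report$descriptor_summary,
       mode_stats = list(
         by_mode = report$mode_stats$by_mode,
         top_mode = report$mode_stats$top_mode,
         eigenvalues = report$mode_stats$eigenvalues,
         permutation = report$mode_stats$permutation),
       pockets = report$pockets,
       provenance = report$provenance)
}

#' Read back a pipeline report
#'
#' @param path a `report.json` file (or the directory holding it).
#' @return the parsed report list.
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.kd_report <- function(x, ...) {
  cat(sprintf("<kd_report> %d states: %s\n", length(x$states),
              paste(x$states, collapse = ", ")))
  for (s in x$states) {
    fp <- x$fingerprints[[s]]
    cat(sprintf("  %-6s DFG %-11s alphaC %-12s bridge %.2f\n", s,
                fp$dominant_dfg, fp$dominant_alphaC, fp$saltbridge_occupancy))
  }
  invisible(x)
}
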