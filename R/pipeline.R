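#' Default run configuration
#'
#' Central configuration for the simulate / fit / classify / structure /
#' report pipeline. Defaults mirror the study conditions: 51 trajectories
#' (23 completed, 28 stuck) of 1 ns sampled at 1 ps, the published ChCry4
#' time constants, completion threshold 0.3 on TrpC/TrpD, and a 5 A water
#' cutoff. The configuration round-trips losslessly through YAML.
#'
#' @param ... Named overrides of the defaults (unknown names error).
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 42L,
    t_max = 1000,
    dt_sample = 1,
    tau_ps = list(tau_fAB = 23, tau_bAB = 141, tau_fBC = 149,
                  tau_bBC = 82, tau_fCD = 57, tau_bCD = 240),
    n_completed = 23L,
    n_stuck = 28L,
    sigma = 0,
    smooth_window = 0,
    threshold = 0.3,
    water_cutoff = 5,
    edge_pair = c(373L, 319L),
    n_starts = 16L,
    fit_max_iter = 200L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste("unknown config field(s):", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  pos <- c("t_max", "dt_sample", "threshold", "water_cutoff", "n_starts")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(paste("config field", f, "must be positive"))
    }
  }
  if (any(unlist(cfg$tau_ps) <= 0)) abort("time constants must be positive")
  if (cfg$sigma < 0) abort("sigma must be >= 0")
  if (cfg$n_completed + cfg$n_stuck < 1) {
    abort("at least one trajectory required")
  }
  cfg
}

config_rates <- function(cfg) {
  do.call(rates_from_tau, cfg$tau_ps)
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  do.call(default_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg A `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Simulate stage: generate a labelled ensemble and write it out
#'
#' Generates the completed/stuck KMC mixture of [make_heterogeneous_ensemble()]
#' under the configuration and writes `occupations.csv`, `labels.json` and
#' `meta.json` into `out_dir`.
#'
#' @param cfg A `run_config` (default [default_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The generated `hop_ensemble`, invisibly.
#' @export
run_simulate <- function(cfg = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message(sprintf("simulate: seed %d, %d completed + %d stuck, %g ps at %g ps",
                  cfg$seed, cfg$n_completed, cfg$n_stuck,
                  cfg$t_max, cfg$dt_sample))
  ens <- make_heterogeneous_ensemble(
    rates_completed = config_rates(cfg),
    n_completed = cfg$n_completed, n_stuck = cfg$n_stuck,
    t_max = cfg$t_max, dt_sample = cfg$dt_sample,
    sigma = cfg$sigma, seed = cfg$seed,
    smooth_window = cfg$smooth_window, threshold = cfg$threshold
  )
  write_occupations(ens, file.path(out_dir, "occupations.csv"))
  write_labels_json(ens, file.path(out_dir, "labels.json"))
  jsonlite::write_json(ens$meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ens)
}

#' Fit stage: average a subset of traces and extract the rate constants
#'
#' Reads an occupation CSV, averages the selected traces and fits the
#' six-rate chain model, writing a fit JSON (rates in 1/ps plus mirrored
#' time constants in ps).
#'
#' @param occ_path Occupation CSV (canonical schema).
#' @param out_path Output JSON path (`NULL` to skip writing).
#' @param subset `"all"`, `"completed"`, `"stuck"`, or an explicit vector
#'   of `sim_id`s. The label subsets need `labels_path`.
#' @param labels_path Labels JSON (required for label subsets).
#' @param cfg A `run_config` supplying seed and fit options.
#' @return The `kinetic_fit`, invisibly.
#' @export
run_fit <- function(occ_path, out_path = NULL, subset = "all",
                    labels_path = NULL, cfg = default_config()) {
  occ <- read_occupations(occ_path)
  ids <- unique(occ$sim_id)
  if (is.character(subset) && length(subset) == 1 &&
      subset %in% c("all", "completed", "stuck")) {
    if (subset != "all") {
      if (is.null(labels_path)) {
        abort("labels_path is required for subset = completed/stuck")
      }
      labels <- read_labels_json(labels_path)
      ids <- labels$sim_id[labels$label == subset]
      if (length(ids) == 0) abort(paste("no traces labelled", subset))
    }
  } else {
    unknown <- setdiff(subset, ids)
    if (length(unknown) > 0) {
      abort(sprintf("unknown sim_id(s) %s; valid ids: %s",
                    paste(unknown, collapse = ", "),
                    paste(utils::head(ids, 20), collapse = ", ")))
    }
    ids <- subset
  }
  message(sprintf("fit: averaging %d trace(s), %d starts, seed %d",
                  length(ids), cfg$n_starts, cfg$seed))
  avg <- ensemble_mean(occ, subset = ids)
  fit <- fit_rates(avg, n_starts = cfg$n_starts, seed = cfg$seed,
                   max_iter = cfg$fit_max_iter)
  if (!fit$converged) message("fit: no start converged")
  if (!is.null(out_path)) write_fit_json(fit, out_path)
  invisible(fit)
}

#' Classify stage: completed/stuck labels and counts
#'
#' Classifies every trace of an occupation CSV and writes
#' `labels_out.json` plus a one-row summary CSV
#' (`n_total,n_completed,n_stuck,threshold`).
#'
#' @param occ_path Occupation CSV.
#' @param out_dir Output directory.
#' @param cfg A `run_config` supplying the threshold.
#' @return The `classification_result`, invisibly.
#' @export
run_classify <- function(occ_path, out_dir, cfg = default_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  occ <- read_occupations(occ_path)
  res <- classify_ensemble(occ, threshold = cfg$threshold)
  write_labels_json(res$per_sim, file.path(out_dir, "labels_out.json"))
  readr::write_csv(
    tibble(n_total = res$n_completed + res$n_stuck,
           n_completed = res$n_completed, n_stuck = res$n_stuck,
           threshold = res$threshold),
    file.path(out_dir, "classification_summary.csv"))
  invisible(res)
}

#' Structure stage: water counts, edge distances and the Gaussian fit
#'
#' Reads PDB frames and writes per-frame water counts for each tetrad
#' residue (`water_counts[_tag].csv`), per-frame edge-to-edge distances of
#' the configured pair (`edge_distances[_tag].csv`), and — when at least
#' 30 frames are available — the Gaussian distance-distribution fit
#' (`distance_distribution[_tag].json`).
#'
#' @param pdb_path Input PDB (multi-MODEL supported).
#' @param out_dir Output directory.
#' @param cfg A `run_config` supplying the cutoff and residue pair.
#' @param tag Optional file-name tag, e.g. `"completed"` or `"stuck"`.
#' @return List with the water-count and distance tibbles and the
#'   `distance_distribution` (or `NULL`), invisibly.
#' @export
run_structure <- function(pdb_path, out_dir, cfg = default_config(),
                          tag = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sfx <- if (is.null(tag)) "" else paste0("_", tag)
  frames <- read_frames(pdb_path)
  present <- intersect(trp_sites()$residue_number,
                       unique(frames$res_number[!frames$is_water]))
  waters <- purrr::map_dfr(present, function(rn) {
    count_waters_near(frames, rn, cutoff = cfg$water_cutoff)
  }) |> dplyr::rename(residue = "res_number",
                      water_count = "water_count")
  readr::write_csv(waters[, c("frame", "residue", "water_count")],
                   file.path(out_dir, paste0("water_counts", sfx, ".csv")))
  dist <- edge_to_edge(frames, cfg$edge_pair[1], cfg$edge_pair[2])
  readr::write_csv(dist[, c("frame", "distance_A")],
                   file.path(out_dir, paste0("edge_distances", sfx, ".csv")))
  dd <- NULL
  if (nrow(dist) >= 30) {
    dd <- fit_distance_distribution(dist$distance_A)
    write_distribution_json(
      dd, file.path(out_dir, paste0("distance_distribution", sfx, ".json")))
  }
  invisible(list(water_counts = waters, edge_distances = dist,
                 distribution = dd))
}

#' Report stage: one machine-readable summary of a run directory
#'
#' Collects the stage outputs present in `run_dir` into `report.json`
#' (plus `report_time_constants.csv`): the fitted time-constant table,
#' classification counts, per-residue water-count means split by tag, and
#' the Gaussian distance-fit parameters per tag. Every number is read back
#' from a stage output file; regenerating the report from the same inputs
#' is byte-identical.
#'
#' @param run_dir Directory holding stage outputs (`fit.json`,
#'   `classification_summary.csv`, `water_counts*.csv`,
#'   `distance_distribution*.json`).
#' @param out_path Output JSON path (default `report.json` in `run_dir`).
#' @return The report list, invisibly.
#' @export
run_report <- function(run_dir, out_path = file.path(run_dir, "report.json")) {
  need <- c(fit = "fit.json",
            classification = "classification_summary.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0) {
    abort(paste("missing stage output(s) in", run_dir, ":",
                paste(sprintf("%s (%s)", missing, names(missing)),
                      collapse = ", ")))
  }
  fit <- jsonlite::read_json(file.path(run_dir, "fit.json"),
                             simplifyVector = TRUE)
  cls <- readr::read_csv(file.path(run_dir, "classification_summary.csv"),
                         show_col_types = FALSE)

  water_files <- list.files(run_dir, "^water_counts.*\\.csv$",
                            full.names = TRUE)
  waters <- purrr::map(stats::setNames(
    water_files,
    gsub("^water_counts_?|\\.csv$", "", basename(water_files))),
    function(f) {
      readr::read_csv(f, show_col_types = FALSE) |>
        group_by(.data$residue) |>
        summarise(mean_water_count = mean(.data$water_count),
                  .groups = "drop")
    })
  dist_files <- list.files(run_dir, "^distance_distribution.*\\.json$",
                           full.names = TRUE)
  gaussians <- purrr::map(stats::setNames(
    dist_files,
    gsub("^distance_distribution_?|\\.json$", "", basename(dist_files))),
    function(f) jsonlite::read_json(f, simplifyVector = TRUE)$gaussian)

  tau_tbl <- tibble(term = names(fit$tau_ps),
                    tau_ps = as.numeric(unlist(fit$tau_ps)))
  report <- list(
    time_constants_ps = as.list(stats::setNames(tau_tbl$tau_ps,
                                                tau_tbl$term)),
    fit_converged = isTRUE(fit$converged),
    classification = as.list(cls[1, ]),
    water_count_means = purrr::map(waters, function(w) {
      as.list(stats::setNames(w$mean_water_count, as.character(w$residue)))
    }),
    gaussian_distance_fits = gaussians
  )
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  readr::write_csv(tau_tbl, file.path(run_dir, "report_time_constants.csv"))
  invisible(report)
}
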