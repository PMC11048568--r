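#' Classify a single trajectory as completed or stuck
#'
#' A trajectory is "completed" when the hole occupation on TrpC or TrpD
#' reaches at least `threshold` at some sampled time instant, otherwise it
#' is "stuck" (hole confined to TrpA/TrpB). The comparison uses a closed
#' boundary (`>=`): an occupation of exactly the threshold counts as
#' completed. Every sampled time point is scanned, not just the final one.
#'
#' @param trace Occupation tibble (`time_ps`, `occ_A..occ_D`).
#' @param threshold Completion threshold (default 0.3).
#' @param sites Criterion sites (default C and D).
#' @return `"completed"` or `"stuck"`.
#' @export
classify_completion <- function(trace, threshold = 0.3,
                                sites = c("C", "D")) {
  trace <- validate_trace(trace, quiet = TRUE)
  sites <- match.arg(sites, SITE_LABELS, several.ok = TRUE)
  peak <- max(as.matrix(trace[paste0("occ_", sites)]))
  if (peak >= threshold) "completed" else "stuck"
}

#' Classify every trajectory of an ensemble
#'
#' Applies [classify_completion()] per trace and tallies the two classes.
#' When the ensemble carries ground-truth labels (e.g. from
#' [make_heterogeneous_ensemble()]), the agreement fraction between
#' predicted and true labels is reported as well.
#'
#' @param ensemble A `hop_ensemble` or tidy occupation tibble.
#' @param threshold,sites Passed to [classify_completion()].
#' @return A `classification_result`: tibble `per_sim`
#'   (`sim_id, label[, true_label]`), counts `n_completed`/`n_stuck`,
#'   the `threshold`, criterion `sites`, and `agreement` (fraction, or
#'   `NA` without ground truth).
#' @export
classify_ensemble <- function(ensemble, threshold = 0.3,
                              sites = c("C", "D")) {
  occ <- as_occupations(ensemble)
  if (nrow(occ) == 0) abort("ensemble is empty")
  sites <- match.arg(sites, SITE_LABELS, several.ok = TRUE)
  site_cols <- paste0("occ_", sites)
  per_sim <- occ |>
    group_by(.data$sim_id) |>
    summarise(peak = max(dplyr::pick(all_of(site_cols))), .groups = "drop") |>
    mutate(label = ifelse(.data$peak >= threshold, "completed", "stuck")) |>
    select(all_of(c("sim_id", "label")))

  agreement <- NA_real_
  if (inherits(ensemble, "hop_ensemble") && !is.null(ensemble$labels)) {
    truth <- ensemble$labels
    per_sim <- left_join(per_sim,
                         dplyr::rename(truth, true_label = "label"),
                         by = "sim_id")
    agreement <- mean(per_sim$label == per_sim$true_label)
  }
  structure(
    list(per_sim = per_sim,
         n_completed = sum(per_sim$label == "completed"),
         n_stuck = sum(per_sim$label == "stuck"),
         threshold = threshold,
         sites = sites,
         agreement = agreement),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> %d completed / %d stuck (threshold %.2f on %s)\n",
    x$n_completed, x$n_stuck, x$threshold, paste(x$sites, collapse = "/")))
  if (!is.na(x$agreement)) {
    cat(sprintf("  agreement with ground truth: %.1f%%\n", 100 * x$agreement))
  }
  invisible(x)
}

#' Tidy a classification result
#'
#' @param x A `classification_result`.
#' @param ... Unused.
#' @return The per-simulation label tibble.
#' @method tidy classification_result
#' @export
tidy.classification_result <- function(x, ...) x$per_sim

#' @method glance classification_result
#' @export
glance.classification_result <- function(x, ...) {
  tibble(n_total = x$n_completed + x$n_stuck,
         n_completed = x$n_completed, n_stuck = x$n_stuck,
         threshold = x$threshold, agreement = x$agreement)
}

#' Pointwise mean and spread of a series collection
#'
#' Reduces a collection of per-simulation series (occupations, site
#' energies or couplings, identified by `sim_id` on a shared grid) to the
#' pointwise mean and standard deviation per series column — the summary
#' behind mean-plus-band plots. The population standard deviation
#' (divisor n) is used by default since the band describes the ensemble
#' itself rather than estimating a wider population.
#'
#' @param series Tidy tibble: `sim_id`, `time_ps`, plus one column per
#'   series (e.g. `occ_A..occ_D`, `eps_A..eps_D` or `T_AB..T_CD`).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A tibble `time_ps, <name>_mean, <name>_sd, ...` with attribute
#'   `n` = number of contributing simulations.
#' @export
summarize_series <- function(series, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  series <- as_occupations(series)
  if (nrow(series) == 0) abort("series collection is empty")
  value_cols <- setdiff(names(series), c("sim_id", "time_ps"))
  if (length(value_cols) == 0) abort("no series columns found")
  counts <- series |> dplyr::count(.data$time_ps)
  if (length(unique(counts$n)) != 1L) {
    abort("all series must share one time grid")
  }
  n <- counts$n[1]
  pop_sd <- function(x) {
    m <- mean(x)
    sqrt(mean((x - m)^2))
  }
  sd_fun <- if (sd_type == "population") pop_sd else stats::sd
  out <- series |>
    group_by(.data$time_ps) |>
    summarise(across(all_of(value_cols),
                     list(mean = mean, sd = sd_fun),
                     .names = "{.col}_{.fn}"),
              .groups = "drop") |>
    arrange(.data$time_ps)
  attr(out, "n") <- n
  out
}

#' Compare a quantity across all / completed / stuck subsets
#'
#' Splits an ensemble by a classification and summarises the requested
#' quantity for the full ensemble and each class on the shared grid, for
#' side-by-side band plots of completed vs stuck trajectories.
#'
#' @param ensemble A `hop_ensemble`.
#' @param result A `classification_result` covering the ensemble (default:
#'   computed on the fly).
#' @param quantity `"occupations"`, `"energies"` or `"couplings"`. Site
#'   energies / couplings are taken from `ensemble$site_energies` /
#'   `ensemble$couplings` (tidy tibbles with `sim_id`); when the requested
#'   quantity is not attached the comparison is flagged absent rather than
#'   erroring.
#' @return A `subset_comparison`: `summary` tibble with a `subset` column
#'   (`all`/`completed`/`stuck`), `quantity`, and `absent` — `TRUE` when
#'   the quantity is unavailable, plus the names of empty subsets.
#' @export
compare_subsets <- function(ensemble,
                            result = classify_ensemble(ensemble),
                            quantity = c("occupations", "energies",
                                         "couplings")) {
  quantity <- match.arg(quantity)
  data <- switch(quantity,
                 occupations = as_occupations(ensemble),
                 energies = ensemble$site_energies,
                 couplings = ensemble$couplings)
  if (is.null(data)) {
    return(structure(list(summary = NULL, quantity = quantity,
                          absent = TRUE, empty_subsets = character()),
                     class = "subset_comparison"))
  }
  data <- as_tibble(data)
  ids <- list(
    all = result$per_sim$sim_id,
    completed = filter(result$per_sim, .data$label == "completed")$sim_id,
    stuck = filter(result$per_sim, .data$label == "stuck")$sim_id
  )
  empty <- names(ids)[vapply(ids, length, integer(1)) == 0]
  pieces <- purrr::imap(ids[setdiff(names(ids), empty)], function(sel, nm) {
    summarize_series(filter(data, .data$sim_id %in% sel)) |>
      mutate(subset = nm, .before = 1)
  })
  structure(list(summary = dplyr::bind_rows(pieces), quantity = quantity,
                 absent = FALSE, empty_subsets = empty),
            class = "subset_comparison")
}

#' @export
print.subset_comparison <- function(x, ...) {
  if (x$absent) {
    cat(sprintf("<subset_comparison> %s: absent (not loaded)\n", x$quantity))
  } else {
    cat(sprintf("<subset_comparison> %s over subsets: %s\n", x$quantity,
                paste(unique(x$summary$subset), collapse = ", ")))
    if (length(x$empty_subsets) > 0) {
      cat("  empty subsets:", paste(x$empty_subsets, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Plot occupation traces or an ensemble mean
#'
#' @param x Occupation tibble (single trace or with `sim_id`) or a
#'   `hop_ensemble`, in which case the ensemble mean is drawn over the
#'   per-trace curves.
#' @return A ggplot of per-site occupation vs time.
#' @export
plot_occupations <- function(x) {
  occ <- as_occupations(x)
  long <- pivot_occ(occ)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ps,
                                          y = .data$occupation,
                                          colour = .data$site))
  if (length(unique(occ$sim_id)) > 1L) {
    m <- pivot_occ(ensemble_mean(occ))
    p <- p +
      ggplot2::geom_line(ggplot2::aes(group = interaction(.data$sim_id,
                                                          .data$site)),
                         alpha = 0.15, linewidth = 0.2) +
      ggplot2::geom_line(data = m, linewidth = 1)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.6)
  }
  p + ggplot2::labs(x = "time (ps)", y = "hole occupation") +
    ggplot2::theme_minimal()
}
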