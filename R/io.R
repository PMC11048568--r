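#' Write occupation traces to CSV
#'
#' Uses the canonical schema `sim_id,time_ps,occ_A,occ_B,occ_C,occ_D`.
#' A single trace without `sim_id` is written with `sim_id = 1`.
#' Occupation values round-trip bit-identically at 12 significant digits.
#'
#' @param x A `hop_ensemble` or occupation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occupations <- function(x, path) {
  occ <- as_occupations(x)
  readr::write_csv(occ[, c("sim_id", "time_ps", OCC_COLS)], path)
  invisible(path)
}

#' Read occupation traces from CSV
#'
#' @param path CSV with header `sim_id,time_ps,occ_A,occ_B,occ_C,occ_D`.
#' @param validate Renormalise per-time sums via [validate_trace()]
#'   (default `TRUE`).
#' @return A tidy occupation tibble.
#' @export
read_occupations <- function(path, validate = TRUE) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  occ <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sim_id", "time_ps", OCC_COLS)
  missing <- setdiff(need, names(occ))
  if (length(missing) > 0) {
    abort(paste("occupation CSV lacks column(s):",
                paste(missing, collapse = ", ")))
  }
  if (validate) {
    occ <- occ |>
      group_by(.data$sim_id) |>
      dplyr::group_modify(function(tr, key) {
        validate_trace(tr, quiet = TRUE)
      }) |>
      ungroup()
  }
  occ
}

#' Write ensemble labels to JSON
#'
#' @param labels Tibble `sim_id, label` (or a labelled `hop_ensemble`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels_json <- function(labels, path) {
  if (inherits(labels, "hop_ensemble")) labels <- labels$labels
  if (is.null(labels)) abort("no labels to write")
  obj <- as.list(stats::setNames(labels$label, as.character(labels$sim_id)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read ensemble labels from JSON
#'
#' @param path File written by [write_labels_json()].
#' @return Tibble `sim_id, label`.
#' @export
read_labels_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble(sim_id = as.integer(names(obj)), label = unname(unlist(obj))) |>
    arrange(.data$sim_id)
}

#' Write site-energy or coupling series to CSV
#'
#' Schema `sim_id,time_ps,<series...>` with series columns `eps_A..eps_D`
#' or `T_AB,T_BC,T_CD`.
#'
#' @param series Tidy series tibble (with or without `sim_id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  series <- as_tibble(series)
  if (!"sim_id" %in% names(series)) {
    series <- mutate(series, sim_id = 1L, .before = 1)
  }
  readr::write_csv(series, path)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a kinetic fit to JSON
#'
#' Records both the rates (1/ps) and the mirrored time constants (ps),
#' plus fit diagnostics.
#'
#' @param fit A `kinetic_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- c(
    as.list(unclass(fit$rates)),
    list(tau_ps = as.list(fit$tau_ps),
         residual_norm = fit$residual_norm,
         n_points = fit$n_points,
         converged = fit$converged,
         per_parameter_spread = as.list(fit$per_parameter_spread))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
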