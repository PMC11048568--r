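# residue names recognised as water, extensible via the functions' args
WATER_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read coordinate frames from a PDB file
#'
#' Parses a (possibly multi-MODEL) PDB file into one tidy atom table with
#' a `frame` column, one frame per MODEL (a single frame when no MODEL
#' records are present). Parsing is delegated to `bio3d::read.pdb`; a
#' light pre-scan reports the line number of malformed ATOM/HETATM
#' records.
#'
#' @param path PDB file path.
#' @param water_resnames Residue names treated as water by downstream
#'   analyses (default HOH/WAT/SOL/TIP3), recorded as an attribute.
#' @return A tibble with columns `frame` (1-based), `serial`, `atom_name`,
#'   `res_name`, `res_number`, `chain`, `x`, `y`, `z` (Angstrom),
#'   `element`, `is_water`.
#' @export
read_frames <- function(path, water_resnames = WATER_RESNAMES) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste("empty PDB file:", path))
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) abort(paste("no ATOM/HETATM records in", path))
  for (i in which(rec)) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (nchar(ln) < 54 || any(is.na(coords))) {
      abort(sprintf("malformed ATOM/HETATM record at line %d of %s", i, path))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_atoms <- nrow(at)
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)

  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  }
  frames <- purrr::map(seq_len(n_frames), function(f) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    tibble(
      frame = f,
      serial = at$eleno,
      atom_name = at$elety,
      res_name = at$resid,
      res_number = at$resno,
      chain = at$chain,
      x = co[, 1], y = co[, 2], z = co[, 3],
      element = elem
    )
  })
  out <- dplyr::bind_rows(frames) |>
    mutate(is_water = .data$res_name %in% water_resnames)
  attr(out, "water_resnames") <- water_resnames
  attr(out, "n_frames") <- n_frames
  out
}

frame_subset <- function(frames, f) {
  filter(frames, .data$frame == f)
}

residue_atoms <- function(fr, res_number, heavy_only = TRUE) {
  res <- filter(fr, .data$res_number == !!res_number, !.data$is_water)
  if (nrow(res) == 0) {
    abort(sprintf("residue %d not found in frame", res_number))
  }
  if (heavy_only) res <- filter(res, toupper(.data$element) != "H")
  res
}

# squared-distance matrix between two coordinate sets (n x 3 each)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
}

#' Count water molecules near a residue
#'
#' Counts, per frame, the distinct water molecules having any atom
#' (hydrogens included) within `cutoff` of any heavy atom of the given
#' residue. The boundary is closed: a water at exactly the cutoff is
#' counted. Each water molecule is counted once regardless of how many of
#' its atoms fall inside the shell. No periodic images are considered:
#' frames are assumed wrapped around the protein.
#'
#' @param frames Atom table from [read_frames()] (or one frame of it).
#' @param res_number Residue number of the target residue (e.g. 373 for
#'   TrpB of ChCry4).
#' @param cutoff Shell radius in Angstrom (default 5).
#' @return Tibble `frame, res_number, water_count`.
#' @export
count_waters_near <- function(frames, res_number, cutoff = 5.0) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  frames <- as_tibble(frames)
  purrr::map_dfr(sort(unique(frames$frame)), function(f) {
    fr <- frame_subset(frames, f)
    res <- residue_atoms(fr, res_number, heavy_only = TRUE)
    waters <- filter(fr, .data$is_water)
    if (nrow(waters) == 0) {
      return(tibble(frame = f, res_number = res_number, water_count = 0L))
    }
    d2 <- cross_dist2(as.matrix(waters[, c("x", "y", "z")]),
                      as.matrix(res[, c("x", "y", "z")]))
    near <- apply(d2 <= cutoff^2 + 1e-9, 1, any)
    n <- length(unique(paste(waters$chain[near], waters$res_number[near])))
    tibble(frame = f, res_number = res_number, water_count = n)
  })
}

#' Edge-to-edge distance between two residues
#'
#' The minimum Euclidean distance between side-chain heavy atoms of the
#' two residues, the edge distance that enters distance-dependent
#' electron-transfer rate estimates. Backbone atoms (N, CA, C, O, OXT) and
#' hydrogens are excluded by default; `mode = "all_heavy"` includes the
#' backbone.
#'
#' @param frames Atom table from [read_frames()].
#' @param res_a,res_b Residue numbers (must differ).
#' @param mode `"sidechain"` (default) or `"all_heavy"`.
#' @return Tibble `frame, res_a, res_b, distance_A` (Angstrom).
#' @export
edge_to_edge <- function(frames, res_a, res_b,
                         mode = c("sidechain", "all_heavy")) {
  mode <- match.arg(mode)
  if (res_a == res_b) abort("res_a and res_b must differ")
  frames <- as_tibble(frames)
  pick_atoms <- function(fr, rn) {
    res <- residue_atoms(fr, rn, heavy_only = TRUE)
    if (mode == "sidechain") {
      res <- filter(res, !.data$atom_name %in% BACKBONE_ATOMS)
    }
    if (nrow(res) == 0) {
      abort(sprintf("residue %d has no usable heavy atoms", rn))
    }
    res
  }
  purrr::map_dfr(sort(unique(frames$frame)), function(f) {
    fr <- frame_subset(frames, f)
    a <- pick_atoms(fr, res_a)
    b <- pick_atoms(fr, res_b)
    d2 <- cross_dist2(as.matrix(a[, c("x", "y", "z")]),
                      as.matrix(b[, c("x", "y", "z")]))
    tibble(frame = f, res_a = res_a, res_b = res_b,
           distance_A = sqrt(max(0, min(d2))))
  })
}

#' Histogram a distance sample and fit a single Gaussian
#'
#' Bins the samples into a normalised density histogram and fits
#' `a * exp(-(x - m)^2 / (2 s^2))` to the bin centres by least squares;
#' the fitted mean `m` is reported as the location of the distribution
#' maximum. Bin count defaults to the Freedman-Diaconis rule.
#'
#' @param samples Distance samples in Angstrom (at least 30).
#' @param n_bins Number of histogram bins (`NULL` = Freedman-Diaconis,
#'   minimum 5).
#' @return A `distance_distribution`: `samples`, `bin_edges`, `density`
#'   (integrates to 1 over the binned range), `gaussian` (named
#'   `amplitude`, `mean`, `sd`) and `fit_ok`. Degenerate samples (zero
#'   variance) give `fit_ok = FALSE`.
#' @export
fit_distance_distribution <- function(samples, n_bins = NULL) {
  samples <- as.numeric(samples)
  samples <- samples[is.finite(samples)]
  if (length(samples) < 30) abort("need at least 30 distance samples")
  if (!is.null(n_bins) && n_bins < 5) abort("n_bins must be >= 5")

  if (stats::sd(samples) < 1e-12) {
    return(structure(list(samples = samples, bin_edges = NULL,
                          density = NULL, gaussian = NULL, fit_ok = FALSE),
                     class = "distance_distribution"))
  }
  if (is.null(n_bins)) {
    n_bins <- max(5L, grDevices::nclass.FD(samples))
  }
  h <- graphics::hist(samples,
                      breaks = seq(min(samples), max(samples),
                                   length.out = n_bins + 1),
                      plot = FALSE)
  centers <- h$mids
  dens <- h$density

  m0 <- mean(samples)
  s0 <- stats::sd(samples)
  a0 <- max(dens)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dens ~ a * exp(-(centers - m)^2 / (2 * s^2)),
      start = list(a = a0, m = m0, s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    gaussian <- NULL
    fit_ok <- FALSE
  } else {
    cf <- stats::coef(fit)
    gaussian <- c(amplitude = unname(cf["a"]), mean = unname(cf["m"]),
                  sd = abs(unname(cf["s"])))
    fit_ok <- is.finite(gaussian[["sd"]]) && gaussian[["sd"]] > 0
  }
  structure(list(samples = samples, bin_edges = h$breaks, density = dens,
                 gaussian = gaussian, fit_ok = fit_ok),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("<distance_distribution>", length(x$samples), "samples\n")
  if (x$fit_ok) {
    cat(sprintf("  Gaussian fit: mean %.3f A, sd %.3f A\n",
                x$gaussian[["mean"]], x$gaussian[["sd"]]))
  } else {
    cat("  Gaussian fit failed (degenerate samples?)\n")
  }
  invisible(x)
}

#' @method glance distance_distribution
#' @export
glance.distance_distribution <- function(x, ...) {
  tibble(
    n = length(x$samples),
    mean_A = if (x$fit_ok) x$gaussian[["mean"]] else NA_real_,
    sd_A = if (x$fit_ok) x$gaussian[["sd"]] else NA_real_,
    amplitude = if (x$fit_ok) x$gaussian[["amplitude"]] else NA_real_,
    fit_ok = x$fit_ok
  )
}

#' Plot a distance distribution with its Gaussian fit
#'
#' @param object A `distance_distribution`.
#' @param ... Unused.
#' @return A ggplot of the density histogram and fitted curve.
#' @method autoplot distance_distribution
#' @export
autoplot.distance_distribution <- function(object, ...) {
  df <- tibble(distance_A = object$samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_A)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            breaks = object$bin_edges,
                            fill = "grey80", colour = "grey40") +
    ggplot2::labs(x = "edge-to-edge distance (Å)", y = "density") +
    ggplot2::theme_minimal()
  if (object$fit_ok) {
    g <- object$gaussian
    xs <- seq(min(object$bin_edges), max(object$bin_edges), length.out = 200)
    curve_df <- tibble(distance_A = xs,
                       density = g[["amplitude"]] *
                         exp(-(xs - g[["mean"]])^2 / (2 * g[["sd"]]^2)))
    p <- p + ggplot2::geom_line(data = curve_df,
                                ggplot2::aes(y = .data$density),
                                colour = "firebrick", linewidth = 0.9)
  }
  p
}

#' Serialise a distance distribution to JSON
#'
#' @param x A `distance_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution_json <- function(x, path) {
  obj <- list(
    n = length(x$samples),
    bin_edges = x$bin_edges,
    density = x$density,
    gaussian = if (x$fit_ok) as.list(x$gaussian) else NULL,
    fit_ok = x$fit_ok
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
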