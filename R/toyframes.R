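# Idealised tryptophan template: indole ring in the z = 0 plane, CB/CA/N/C/O
# lifted out of plane. Bond lengths ~1.34-1.53 A. Chemistry is approximate;
# the fixtures exist to carry exactly known distances, not real geometry.
trp_template <- function() {
  tibble(
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "NE1", "CE2",
                  "CD2", "CE3", "CZ3", "CH2", "CZ2"),
    x = c(-1.450, -0.473, 0.700, 1.200, -0.761, 0.000, 1.376, 1.806,
          0.754, -0.398, -1.726, -1.897, -0.775, 0.562),
    y = c(-3.400, -2.600, -3.200, -4.000, -1.217, 0.000, 0.000, 1.303,
          2.132, 1.354, 1.782, 3.148, 3.959, 3.510),
    z = c(1.400, 0.900, 1.200, 0.600, 0.400, 0.000, 0.000, 0.000,
          0.000, 0.000, 0.000, 0.000, 0.000, 0.000),
    element = c("N", "C", "C", "O", "C", "C", "C", "N", "C",
                "C", "C", "C", "C", "C")
  )
}

SIDECHAIN_ATOMS <- c("CB", "CG", "CD1", "NE1", "CE2", "CD2", "CE3",
                     "CZ3", "CH2", "CZ2")

min_pair_dist <- function(a, b) {
  sqrt(max(0, min(cross_dist2(a, b))))
}

#' Generate toy multi-frame PDB fixtures with known ground truth
#'
#' Writes a minimal but valid PDB file containing the four tryptophan
#' side chains of the tetrad (residues 396, 373, 319, 370 by default, in
#' chain order A-B-C-D along x) plus water molecules placed at exactly
#' specified minimum distances from specified residues. Consecutive
#' residues are positioned so that their minimum side-chain heavy-atom
#' separation equals `min_separation` to 1e-9 (solved by root finding).
#' Additional frames are rigid-body rotations/translations of the same
#' scene, so all internal distances are frame-invariant. The exact
#' construction parameters and brute-force-verified ground truth (water
#' counts at the 5 A cutoff, consecutive edge-to-edge distances) are
#' recorded in a sidecar JSON next to the PDB.
#'
#' @param path Output PDB path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param n_frames Number of MODEL frames (default 1).
#' @param water_placements Data frame `residue, distance, count`: place
#'   `count` waters at exact minimum heavy-atom distance `distance`
#'   (Angstrom, > 0) from the given residue number.
#' @param min_separation Target minimum side-chain heavy-atom distance
#'   between consecutive residues in Angstrom (default 4.2; must exceed
#'   3.4, the in-plane extent of the template).
#' @param residues Residue numbers for the four tryptophans (default the
#'   ChCry4 tetrad 396, 373, 319, 370).
#' @param water_hydrogens Add two hydrogens per water along the outward
#'   ray (default `FALSE`: oxygen-only, crystallographic style).
#' @param seed Seed for the frame rigid transforms.
#' @return Invisibly, a list: `path`, `truth` (the per-frame ground truth
#'   also written to the sidecar, computed by brute force on the rounded
#'   coordinates the file stores), and `frames` — the exact unrounded atom
#'   table in [read_frames()] layout, for precision-sensitive checks that
#'   must not pass through the 0.001-Angstrom PDB quantisation.
#' @export
make_toy_frames <- function(path, n_frames = 1, water_placements = NULL,
                            min_separation = 4.2,
                            residues = c(396L, 373L, 319L, 370L),
                            water_hydrogens = FALSE, seed = 1) {
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (min_separation <= 3.4) {
    abort("min_separation must exceed 3.4 A (template extent)")
  }
  if (length(residues) != 4L) abort("exactly four residue numbers required")

  tmpl <- trp_template()
  sc_idx <- tmpl$atom_name %in% SIDECHAIN_ATOMS
  sc <- as.matrix(tmpl[sc_idx, c("x", "y", "z")])

  # consecutive x-offset giving exactly the requested side-chain separation
  gap_for <- function(target) {
    f <- function(s) {
      shifted <- sc
      shifted[, 1] <- shifted[, 1] + s
      min_pair_dist(sc, shifted) - target
    }
    stats::uniroot(f, c(3.45, target + 40), tol = 1e-12)$root
  }
  gap <- gap_for(min_separation)

  res_tabs <- purrr::map(seq_along(residues), function(i) {
    t2 <- tmpl
    t2$x <- t2$x + (i - 1) * gap
    t2$res_number <- residues[i]
    t2
  })
  protein <- dplyr::bind_rows(res_tabs)
  protein$res_name <- "TRP"

  # waters at exact minimum distances, placed along outward rays from the
  # side-chain centroid (direction mostly +z, fanned in azimuth)
  waters <- list()
  w_res <- 1000L
  if (!is.null(water_placements)) {
    water_placements <- as_tibble(water_placements)
    if (any(water_placements$distance <= 0)) {
      abort("water placement distances must be > 0")
    }
    for (p in seq_len(nrow(water_placements))) {
      rn <- water_placements$residue[p]
      d <- water_placements$distance[p]
      cnt <- water_placements$count[p]
      ri <- which(residues == rn)
      if (length(ri) == 0) abort(sprintf("unknown residue %s", rn))
      res_heavy <- as.matrix(res_tabs[[ri]][, c("x", "y", "z")])
      centroid <- colMeans(res_heavy[sc_idx, , drop = FALSE])
      for (j in seq_len(cnt)) {
        # fan the rays in azimuth and alternate above/below the ring plane
        # so same-placement waters stay well separated at short distances
        phi <- 2 * pi * (j - 1) / max(1, cnt) + 0.37 * p
        side <- if (j %% 2 == 1) 1 else -1
        u <- c(0.35 * cos(phi), 0.35 * sin(phi), side)
        u <- u / sqrt(sum(u^2))
        g <- function(t) {
          pt <- matrix(centroid + t * u, 1)
          min_pair_dist(pt, res_heavy) - d
        }
        t_star <- stats::uniroot(g, c(0, d + 20), tol = 1e-12)$root
        o_pos <- centroid + t_star * u
        w_res <- w_res + 1L
        wt <- tibble(atom_name = "O", x = o_pos[1], y = o_pos[2],
                     z = o_pos[3], element = "O",
                     res_number = w_res, res_name = "HOH")
        if (water_hydrogens) {
          h1 <- o_pos + 0.57 * u
          h2 <- o_pos + 0.98 * u
          wt <- dplyr::bind_rows(wt, tibble(
            atom_name = c("H1", "H2"),
            x = c(h1[1], h2[1]), y = c(h1[2], h2[2]), z = c(h1[3], h2[3]),
            element = "H", res_number = w_res, res_name = "HOH"))
        }
        # construction check: the oxygen is the nearest atom at exactly d
        realised <- min_pair_dist(as.matrix(wt[, c("x", "y", "z")]),
                                  res_heavy)
        if (abs(realised - d) > 1e-9) {
          abort("internal error: water placement missed target distance")
        }
        waters <- c(waters, list(wt))
      }
    }
  }
  scene <- dplyr::bind_rows(c(list(protein), waters))
  scene$chain <- "A"

  # clash check over all atom pairs
  co <- as.matrix(scene[, c("x", "y", "z")])
  d2 <- cross_dist2(co, co)
  diag(d2) <- Inf
  same_res <- outer(scene$res_number, scene$res_number, "==")
  if (any(d2[!same_res] < 1)) {
    abort("clashing placements: atoms from different residues closer than 1 A")
  }

  # frame transforms: identity for frame 1, random rigid motion afterwards
  restore <- local_rng(seed)
  on.exit(restore())
  frames_xyz <- purrr::map(seq_len(n_frames), function(f) {
    if (f == 1) return(co)
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    sweep(co %*% t(Q), 2, stats::runif(3, -5, 5), "+")
  })
  # PDB stores coordinates at 0.001 A; the sidecar truth is computed by
  # brute force on the rounded coordinates actually written, per frame
  rounded_xyz <- purrr::map(frames_xyz, round, digits = 3)

  is_sc <- scene$res_name == "TRP" & scene$atom_name %in% SIDECHAIN_ATOMS
  is_heavy <- scene$element != "H"
  frame_truth <- purrr::map(rounded_xyz, function(rxyz) {
    list(
      consecutive_edge_A = purrr::map_dbl(1:3, function(i) {
        a <- rxyz[is_sc & scene$res_number == residues[i], , drop = FALSE]
        b <- rxyz[is_sc & scene$res_number == residues[i + 1], , drop = FALSE]
        min_pair_dist(a, b)
      }),
      water_counts_5A = stats::setNames(purrr::map_int(
        seq_along(residues), function(i) {
          res_heavy <- rxyz[is_heavy & !scene$res_name %in% "HOH" &
                              scene$res_number == residues[i], , drop = FALSE]
          n <- 0L
          for (wr in unique(scene$res_number[scene$res_name == "HOH"])) {
            wm <- rxyz[scene$res_number == wr & scene$res_name == "HOH", ,
                       drop = FALSE]
            if (min_pair_dist(wm, res_heavy) <= 5) n <- n + 1L
          }
          n
        }), as.character(residues))
    )
  })
  truth <- list(
    n_frames = n_frames,
    residues = as.integer(residues),
    min_separation = min_separation,
    frames = frame_truth,
    placements = if (is.null(water_placements)) list() else water_placements,
    n_waters = length(waters),
    water_hydrogens = water_hydrogens,
    synthetic = TRUE
  )

  write_pdb_frames(path, scene, rounded_xyz)
  jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)

  # exact (unrounded) in-memory frames for precision-sensitive work
  frames_tbl <- purrr::imap_dfr(frames_xyz, function(fc, f) {
    tibble(frame = f, serial = seq_len(nrow(scene)),
           atom_name = scene$atom_name, res_name = scene$res_name,
           res_number = scene$res_number, chain = scene$chain,
           x = fc[, 1], y = fc[, 2], z = fc[, 3],
           element = scene$element,
           is_water = scene$res_name %in% WATER_RESNAMES)
  })
  invisible(list(path = path, truth = truth, frames = frames_tbl))
}

# fixed-width PDB writer for the toy fixtures (multi-MODEL)
write_pdb_frames <- function(path, scene, frames_xyz) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    100, 100, 100, 90, 90, 90), con)
  multi <- length(frames_xyz) > 1
  rec <- ifelse(scene$res_name == "HOH", "HETATM", "ATOM  ")
  for (f in seq_along(frames_xyz)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    co <- frames_xyz[[f]]
    lines <- sprintf(
      "%s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, seq_len(nrow(scene)),
      ifelse(nchar(scene$atom_name) < 4,
             paste0(" ", scene$atom_name), scene$atom_name),
      scene$res_name, scene$chain, scene$res_number,
      co[, 1], co[, 2], co[, 3], 1, 0, scene$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
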