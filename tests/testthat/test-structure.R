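test_that("toy PDB fixtures round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".pdb")
  out <- make_toy_frames(path, n_frames = 2,
                         water_placements = data.frame(
                           residue = 373, distance = 3.0, count = 3),
                         seed = 1)
  fr <- read_frames(path)
  expect_equal(attr(fr, "n_frames"), 2)
  expect_equal(length(unique(fr$frame)), 2)
  # 4 x 14 protein atoms + 3 oxygen-only waters
  expect_equal(nrow(fr) / 2, 4 * 14 + 3)
  expect_equal(sum(fr$is_water) / 2, 3)
  expect_setequal(unique(fr$res_name), c("TRP", "HOH"))

  single <- withr::local_tempfile(fileext = ".pdb")
  make_toy_frames(single, n_frames = 1)
  expect_equal(attr(read_frames(single), "n_frames"), 1)
})

test_that("the reader rejects malformed and empty input", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  TRP A 396      bad coords here",
               "END"), bad)
  expect_error(read_frames(bad), "line 1")

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_frames(empty), "empty")

  nowater_ops <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A1001      10.000  10.000  10.000  1.00  0.00           O",
    "END"), nowater_ops)
  fr <- read_frames(nowater_ops)
  expect_error(count_waters_near(fr, 373), "not found")
})

test_that("water counts follow the any-atom closed-boundary rule", {
  # hand-built frame: residue of two heavy atoms, three waters at known
  # minimum distances 2.0, 4.9 and 5.1
  fr <- tibble::tibble(
    frame = 1L, serial = 1:5,
    atom_name = c("CG", "CD1", "O", "O", "O"),
    res_name = c("TRP", "TRP", "HOH", "HOH", "HOH"),
    res_number = c(373L, 373L, 1001L, 1002L, 1003L),
    chain = "A",
    x = c(0, 1.4, 2.0, 0, 0),
    y = c(0, 0, 0, 4.9, 0),
    z = c(0, 0, 0, 0, 5.1),
    element = c("C", "C", "O", "O", "O"),
    is_water = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(count_waters_near(fr, 373)$water_count, 2L)
  expect_equal(count_waters_near(fr, 373, cutoff = 5.1)$water_count, 3L)

  # hydrogen at 4.8 counts the water even though its oxygen sits at 5.2
  hw <- dplyr::bind_rows(
    fr[1:2, ],
    tibble::tibble(frame = 1L, serial = 6:7, atom_name = c("O", "H1"),
                   res_name = "HOH", res_number = 2001L, chain = "A",
                   x = c(5.2, 4.8), y = 0, z = 0,
                   element = c("O", "H"), is_water = TRUE))
  expect_equal(count_waters_near(hw, 373)$water_count, 1L)

  # exact boundary: water at exactly the cutoff is inside (uses the
  # unrounded in-memory frames, not the 0.001-A-quantised file)
  exact <- make_toy_frames(withr::local_tempfile(fileext = ".pdb"),
                           water_placements = data.frame(
                             residue = 319, distance = 5.0, count = 1))
  expect_equal(count_waters_near(exact$frames, 319)$water_count, 1L)
  expect_error(count_waters_near(fr, 373, cutoff = -1), "cutoff")
})

test_that("water counts and edge distances match brute-force oracles", {
  set.seed(71)
  for (i in 1:10) {
    path <- withr::local_tempfile(fileext = ".pdb")
    make_toy_frames(
      path, n_frames = 2,
      water_placements = data.frame(
        residue = sample(c(396, 373, 319, 370), 2),
        distance = round(runif(2, 2, 7), 2),
        count = sample(1:3, 2, replace = TRUE)),
      min_separation = round(runif(1, 3.6, 6), 2),
      seed = i)
    fr <- read_frames(path)
    for (f in 1:2) {
      for (rn in c(396, 373, 319, 370)) {
        got <- count_waters_near(fr[fr$frame == f, ], rn)$water_count
        expect_identical(got, brute_water_count(fr, f, rn))
      }
      pair <- sample(c(396, 373, 319, 370), 2)
      got <- edge_to_edge(fr[fr$frame == f, ], pair[1], pair[2])$distance_A
      expect_equal(got, brute_edge(fr, f, pair[1], pair[2]))
    }
  }
})

test_that("structural metrics are invariant under rigid motion", {
  # frames beyond the first are random rotations + translations of the
  # same scene, so per-frame results must agree up to coordinate rounding
  path <- withr::local_tempfile(fileext = ".pdb")
  make_toy_frames(path, n_frames = 4,
                  water_placements = data.frame(residue = 373,
                                                distance = 4.0, count = 2),
                  seed = 3)
  fr <- read_frames(path)
  counts <- count_waters_near(fr, 373)$water_count
  expect_true(all(counts == counts[1]))
  d <- edge_to_edge(fr, 373, 319)$distance_A
  expect_lt(max(abs(d - d[1])), 5e-3)
})

test_that("edge-to-edge uses side-chain heavy atoms and validates residues", {
  exact <- make_toy_frames(withr::local_tempfile(fileext = ".pdb"),
                           min_separation = 4.2)
  d <- edge_to_edge(exact$frames, 373, 319)$distance_A
  expect_lt(abs(d - 4.2), 1e-6)
  expect_error(edge_to_edge(exact$frames, 373, 373), "differ")
  expect_error(edge_to_edge(exact$frames, 373, 999), "not found")

  # all-heavy mode may only shrink the distance
  d2 <- edge_to_edge(exact$frames, 396, 373, mode = "all_heavy")$distance_A
  d1 <- edge_to_edge(exact$frames, 396, 373)$distance_A
  expect_lte(d2, d1)
})

test_that("toy generator validates placements and separations", {
  path <- withr::local_tempfile(fileext = ".pdb")
  expect_error(make_toy_frames(path, min_separation = 2), "exceed")
  expect_error(
    make_toy_frames(path, water_placements = data.frame(
      residue = 373, distance = -1, count = 1)),
    "> 0")
  expect_error(
    make_toy_frames(path, water_placements = data.frame(
      residue = 111, distance = 3, count = 1)),
    "unknown residue")
})

test_that("Gaussian distribution fits recover sampling parameters", {
  set.seed(81)
  dd <- fit_distance_distribution(rnorm(1e5, 4.2, 0.2))
  expect_true(dd$fit_ok)
  expect_lt(abs(dd$gaussian[["mean"]] - 4.2), 0.01)
  expect_lt(abs(dd$gaussian[["sd"]] - 0.2), 0.01)
  # histogram density integrates to 1
  widths <- diff(dd$bin_edges)
  expect_lt(abs(sum(dd$density * widths) - 1), 1e-6)

  flat <- fit_distance_distribution(rep(4, 50))
  expect_false(flat$fit_ok)
  expect_error(fit_distance_distribution(rnorm(10)), "at least 30")

  # symmetric bimodal mixture: single-Gaussian mean falls between modes
  set.seed(82)
  mix <- c(rnorm(5e4, 4.0, 0.05), rnorm(5e4, 4.2, 0.05))
  ddm <- fit_distance_distribution(mix)
  expect_gt(ddm$gaussian[["mean"]], 4.0)
  expect_lt(ddm$gaussian[["mean"]], 4.2)

  g <- glance(dd)
  expect_true(g$fit_ok)
  expect_s3_class(autoplot(dd), "ggplot")
})
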