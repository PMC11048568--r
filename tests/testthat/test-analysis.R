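make_trace <- function(peak_site = "occ_C", peak = 0.3, n = 50) {
  tr <- tibble::tibble(time_ps = 0:(n - 1), occ_A = 1, occ_B = 0,
                       occ_C = 0, occ_D = 0)
  mid <- floor(n / 2)
  tr[[peak_site]][mid] <- peak
  tr$occ_A[mid] <- 1 - peak
  tr
}

test_that("completion uses a closed threshold boundary over all time points", {
  expect_equal(classify_completion(make_trace("occ_D", 0.31)), "completed")
  expect_equal(classify_completion(make_trace("occ_C", 0.3)), "completed")
  expect_equal(classify_completion(make_trace("occ_C", 0.299)), "stuck")
  # C and D identically zero
  flat <- tibble::tibble(time_ps = 0:30, occ_A = 0.5, occ_B = 0.5,
                         occ_C = 0, occ_D = 0)
  expect_equal(classify_completion(flat), "stuck")
  # a transient peak counts even if the final state is back on B
  expect_equal(classify_completion(make_trace("occ_C", 0.6)), "completed")
})

test_that("classification is invariant to tolerated renormalisation", {
  tr <- make_trace("occ_C", 0.31)
  scaled <- tr
  occ <- occ_matrix(tr) * 1.04
  scaled[, c("occ_A", "occ_B", "occ_C", "occ_D")] <- as.data.frame(occ)
  expect_equal(classify_completion(scaled), classify_completion(tr))
})

test_that("ensemble classification counts, agreement and order invariance", {
  ens <- make_heterogeneous_ensemble(n_completed = 3, n_stuck = 4,
                                     t_max = 300, seed = 11)
  res <- classify_ensemble(ens)
  expect_equal(res$n_completed, 3)
  expect_equal(res$n_stuck, 4)
  expect_equal(res$agreement, 1)
  expect_equal(res$n_completed + res$n_stuck, nrow(ens$labels))

  # permutation of sim_id order leaves the counts unchanged
  shuffled <- ens$occupations[sample(nrow(ens$occupations)), ]
  res2 <- classify_ensemble(shuffled)
  expect_equal(res2$n_completed, res$n_completed)
  expect_equal(res2$n_stuck, res$n_stuck)

  one <- classify_ensemble(dplyr::filter(ens$occupations, sim_id == 1))
  expect_equal(one$n_completed + one$n_stuck, 1)

  stuck_only <- make_heterogeneous_ensemble(n_completed = 0, n_stuck = 3,
                                            t_max = 100, seed = 11)
  expect_equal(classify_ensemble(stuck_only)$n_completed, 0)

  g <- glance(res)
  expect_equal(g$n_total, 7)
  expect_equal(nrow(tidy(res)), 7)
})

test_that("series summaries give exact closed-form means and bands", {
  two <- tibble::tibble(sim_id = rep(1:2, each = 4),
                        time_ps = rep(0:3, 2),
                        eps_B = rep(c(0.1, 0.3), each = 4))
  s <- summarize_series(two)
  expect_true(all(s$eps_B_mean == 0.2))
  expect_true(all(abs(s$eps_B_sd - 0.1) < 1e-12))
  expect_equal(attr(s, "n"), 2)

  # population vs sample standard deviation
  s2 <- summarize_series(two, sd_type = "sample")
  expect_true(all(abs(s2$eps_B_sd - 0.1 * sqrt(2)) < 1e-12))

  single <- summarize_series(dplyr::filter(two, sim_id == 1))
  expect_true(all(single$eps_B_sd == 0))
  expect_true(all(single$eps_B_mean == 0.1))

  mismatched <- two[-1, ]
  expect_error(summarize_series(mismatched), "share one time grid")
})

test_that("OU ensembles summarise to their specified means", {
  times <- seq(0, 500, 1)
  coll <- purrr::map_dfr(1:51, function(i) {
    dplyr::mutate(
      simulate_site_series(c(T_AB = 0.03, T_BC = 0.01), sd = 0.005,
                           correlation_time = 3, times = times, seed = i),
      sim_id = i, .before = 1)
  })
  s <- summarize_series(coll)
  # standard error of the grand mean across 51 independent OU series
  n_pts <- length(times)
  rho <- exp(-1 / 3)
  var_series_mean <- 0.005^2 / n_pts * (1 + 2 * rho / (1 - rho))
  se_grand <- sqrt(var_series_mean / 51)
  expect_lt(abs(mean(s$T_AB_mean) - 0.03), 3 * se_grand)
  expect_lt(abs(mean(s$T_BC_mean) - 0.01), 3 * se_grand)
})

test_that("subset comparison splits by class and flags absent quantities", {
  ens <- make_heterogeneous_ensemble(n_completed = 3, n_stuck = 4,
                                     t_max = 500, seed = 12)
  res <- classify_ensemble(ens)
  cmp <- compare_subsets(ens, res)
  expect_false(cmp$absent)
  expect_setequal(unique(cmp$summary$subset), c("all", "completed", "stuck"))
  # the stuck class cannot out-populate D at the trajectory end
  final <- dplyr::filter(cmp$summary,
                         time_ps == max(time_ps), subset != "all")
  d_stuck <- final$occ_D_mean[final$subset == "stuck"]
  d_comp <- final$occ_D_mean[final$subset == "completed"]
  expect_lte(d_stuck, d_comp)

  expect_true(compare_subsets(ens, res, quantity = "couplings")$absent)

  # identical traces in both classes give identical summaries
  base <- propagate(ref_rates(), 0:50)
  occ <- dplyr::bind_rows(
    dplyr::mutate(base, sim_id = 1, .before = 1),
    dplyr::mutate(base, sim_id = 2, .before = 1))
  ens2 <- hop_ensemble(occ, labels = tibble::tibble(
    sim_id = 1:2, label = c("completed", "stuck")))
  res2 <- structure(list(per_sim = ens2$labels, n_completed = 1,
                         n_stuck = 1, threshold = 0.3,
                         sites = c("C", "D"), agreement = 1),
                    class = "classification_result")
  cmp2 <- compare_subsets(ens2, res2)
  sums <- split(cmp2$summary[, -1], cmp2$summary$subset)
  expect_equal(sums$completed$occ_D_mean, sums$stuck$occ_D_mean)
  expect_equal(sums$all$occ_B_mean, sums$completed$occ_B_mean)
})
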