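test_that("frozen and absorbing chains behave as constructed", {
  ens <- simulate_kmc(rate_constants(0, 0, 0, 0, 0, 0), t_max = 50,
                      n_traj = 4, seed = 1)
  expect_true(all(ens$occupations$occ_A == 1))

  # fast forward-only chain always ends absorbed at D
  fast <- rate_constants(2, 0, 2, 0, 2, 0)
  ens2 <- simulate_kmc(fast, t_max = 1000, dt_sample = 50, n_traj = 10,
                       seed = 2)
  finals <- dplyr::filter(ens2$occupations, time_ps == 1000)
  expect_true(all(finals$occ_D == 1))

  expect_error(simulate_kmc(ref_rates(), t_max = -1), "t_max")
  expect_error(simulate_kmc(ref_rates(), n_traj = 0), "n_traj")
})

test_that("ensemble mean of many KMC trajectories matches the master equation", {
  n <- 2000
  ens <- simulate_kmc(ref_rates(), t_max = 1000, dt_sample = 1,
                      n_traj = n, seed = 42)
  m <- ensemble_mean(ens)
  ode <- propagate(ref_rates(), 0:1000)
  for (tt in c(100, 500, 1000)) {
    i <- which(m$time_ps == tt)
    p <- unlist(ode[i, -1])
    se <- sqrt(pmax(p * (1 - p), 1e-6) / n)
    expect_true(all(abs(unlist(m[i, -1]) - p) <= 3 * se))
  }
})

test_that("KMC sampling is reproducible and prefix-stable in n_traj", {
  a <- simulate_kmc(ref_rates(), t_max = 100, n_traj = 5, seed = 7)
  b <- simulate_kmc(ref_rates(), t_max = 100, n_traj = 5, seed = 7)
  expect_identical(a$occupations, b$occupations)

  bigger <- simulate_kmc(ref_rates(), t_max = 100, n_traj = 8, seed = 7)
  expect_identical(
    a$occupations,
    dplyr::filter(bigger$occupations, sim_id <= 5))
})

test_that("long single-trajectory time averages approach the equilibrium", {
  ens <- simulate_kmc(ref_rates(), t_max = 2e5, dt_sample = 5,
                      n_traj = 1, seed = 13)
  frac <- colMeans(occ_matrix(ens$occupations))
  ss <- steady_state(ref_rates())
  # effective sample size from the slowest relaxation mode
  lam <- sort(abs(eigen(build_generator(ref_rates()))$values))
  t_corr <- 1 / lam[2]
  n_eff <- 2e5 / (2 * t_corr)
  se <- sqrt(ss * (1 - ss) / n_eff)
  expect_true(all(abs(frac - ss) <= 3 * se))
})

test_that("ensemble_mean handles subsets and trivial cases", {
  ens <- simulate_kmc(ref_rates(), t_max = 20, n_traj = 3, seed = 5)
  single <- ensemble_mean(ens, subset = 2)
  direct <- dplyr::filter(ens$occupations, sim_id == 2)
  expect_equal(occ_matrix(single), occ_matrix(direct))

  two <- tibble::tibble(
    sim_id = rep(1:2, each = 3), time_ps = rep(0:2, 2),
    occ_A = rep(c(1, 0), each = 3), occ_B = rep(c(0, 1), each = 3),
    occ_C = 0, occ_D = 0)
  m <- ensemble_mean(two)
  expect_true(all(m$occ_A == 0.5 & m$occ_B == 0.5 & m$occ_C == 0))

  expect_error(ensemble_mean(ens, subset = integer(0)), "at least one")
  expect_error(ensemble_mean(ens, subset = 99), "unknown sim_id")
})

test_that("observation noise preserves normalisation and matches a clipping oracle", {
  tr <- propagate(ref_rates(), times = 0:200)
  expect_identical(add_observation_noise(tr, 0), tr)
  expect_error(add_observation_noise(tr, -0.1), "sigma")

  noisy <- add_observation_noise(tr, 0.05, seed = 4)
  expect_lt(max(abs(rowSums(occ_matrix(noisy)) - 1)), 1e-9)

  # clipping-bias oracle on a constant (1,0,0,0) trace: direct Monte-Carlo
  # with the same clip-then-renormalise rule
  n <- 1e4
  const <- tibble::tibble(time_ps = 0:(n - 1), occ_A = 1, occ_B = 0,
                          occ_C = 0, occ_D = 0)
  noisy2 <- add_observation_noise(const, 0.05, seed = 8)
  set.seed(1234)
  raw <- cbind(1 + rnorm(n, 0, 0.05), matrix(rnorm(3 * n, 0, 0.05), n))
  raw <- pmin(pmax(raw, 0), 1)
  oracle <- raw / rowSums(raw)
  se <- apply(oracle, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(occ_matrix(noisy2)) - colMeans(oracle)) <=
                    3 * (se + 0.05 / sqrt(n))))
})

test_that("heterogeneous mixtures carry phenotype-consistent labels", {
  ens <- make_heterogeneous_ensemble(n_completed = 4, n_stuck = 5,
                                     t_max = 400, seed = 3)
  expect_equal(nrow(ens$labels), 9)
  expect_equal(sum(ens$labels$label == "completed"), 4)
  # stuck traces can never leave {A, B}: kfBC = 0 by construction
  stuck_ids <- ens$labels$sim_id[ens$labels$label == "stuck"]
  stuck <- dplyr::filter(ens$occupations, sim_id %in% stuck_ids)
  expect_true(all(stuck$occ_C == 0 & stuck$occ_D == 0))
  # completed traces are sampled conditional on reaching C or D
  comp <- dplyr::filter(ens$occupations, !sim_id %in% stuck_ids)
  peak <- comp |> dplyr::group_by(sim_id) |>
    dplyr::summarise(p = max(pmax(occ_C, occ_D)))
  expect_true(all(peak$p >= 0.3))

  all_comp <- make_heterogeneous_ensemble(n_completed = 3, n_stuck = 0,
                                          t_max = 200, seed = 3)
  expect_true(all(all_comp$labels$label == "completed"))
})

test_that("smoothed KMC traces are fractional yet still normalised", {
  ens <- simulate_kmc(ref_rates(), t_max = 300, n_traj = 3, seed = 6,
                      smooth_window = 25)
  occ <- occ_matrix(ens$occupations)
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
  expect_true(any(occ > 0 & occ < 1))
})

test_that("OU series have the requested moments and respect chain topology", {
  times <- seq(0, 1000, 1)
  const <- simulate_site_series(c(eps_A = 0.1), sd = 0,
                                correlation_time = 10, times = times)
  expect_true(all(const$eps_A == 0.1))

  expect_error(
    simulate_site_series(c(T_AC = 0.1), sd = 0.01, correlation_time = 10,
                         times = times),
    "non-neighbour")

  # analytic OU standard error of the sample mean
  long <- simulate_site_series(c(T_BC = 0.1), sd = 0.02,
                               correlation_time = 5,
                               times = seq(0, 1e4, 0.1), seed = 10)
  n <- nrow(long)
  rho <- exp(-0.1 / 5)
  var_mean <- 0.02^2 / n * (1 + 2 * rho / (1 - rho))
  expect_lt(abs(mean(long$T_BC) - 0.1), 3 * sqrt(var_mean))
})
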