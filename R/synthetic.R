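#' Trajectory ensembles
#'
#' An ensemble bundles per-simulation occupation traces on one shared time
#' grid with optional ground-truth labels and generator metadata. The
#' occupations live in a single tidy tibble
#' (`sim_id, time_ps, occ_A..occ_D`), so all dplyr verbs apply directly.
#'
#' @param occupations Tidy occupation tibble.
#' @param labels Optional tibble `sim_id, label` with labels
#'   `"completed"`/`"stuck"`.
#' @param meta Optional list of generator parameters (seed, rates, ...).
#' @return A `hop_ensemble` object.
#' @export
hop_ensemble <- function(occupations, labels = NULL, meta = list()) {
  occupations <- as_tibble(occupations)
  need <- c("sim_id", "time_ps", OCC_COLS)
  missing <- setdiff(need, names(occupations))
  if (length(missing) > 0) {
    abort(paste("ensemble occupations lack column(s):",
                paste(missing, collapse = ", ")))
  }
  grids <- occupations |> group_by(.data$sim_id) |>
    summarise(g = paste(signif(.data$time_ps, 12), collapse = ","),
              .groups = "drop")
  if (length(unique(grids$g)) > 1L) {
    abort("all traces in an ensemble must share one time grid")
  }
  structure(list(occupations = occupations, labels = labels, meta = meta),
            class = "hop_ensemble")
}

#' @export
print.hop_ensemble <- function(x, ...) {
  ns <- length(unique(x$occupations$sim_id))
  nt <- nrow(x$occupations) / ns
  cat(sprintf("<hop_ensemble> %d trajectories x %d time points\n", ns, nt))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels$label)),
                                   table(x$labels$label)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# accept either a hop_ensemble or a bare occupation tibble
as_occupations <- function(x) {
  if (inherits(x, "hop_ensemble")) return(x$occupations)
  x <- as_tibble(x)
  if (!"sim_id" %in% names(x)) x <- mutate(x, sim_id = 1L, .before = 1)
  x
}

#' Kinetic Monte-Carlo trajectory ensemble
#'
#' Stochastic realisation of the four-state chain: each trajectory is a
#' continuous-time Markov jump process on \{A, B, C, D\} (Gillespie
#' algorithm) started at A with the six given rates, sampled on a regular
#' grid as indicator occupations (exactly one site occupied per time
#' point). The ensemble mean of many such trajectories converges to the
#' master-equation solution, playing the role of ensemble-averaged
#' occupation curves. Each trajectory draws from its own RNG substream
#' derived from the master seed, so increasing `n_traj` extends the
#' ensemble without reshuffling earlier trajectories.
#'
#' @param rates A `rate_constants` object. All-zero rates are valid and
#'   give frozen trajectories.
#' @param t_max Trajectory length in ps (default 1000, i.e. 1 ns).
#' @param dt_sample Sampling interval in ps (default 1).
#' @param n_traj Number of trajectories (default 51).
#' @param seed Master seed.
#' @param smooth_window Optional sliding-window width in ps (centred,
#'   partial at the edges). `0` (default) returns raw indicators; a
#'   positive window yields fractional per-trace occupations mimicking
#'   quantum populations.
#' @return A `hop_ensemble`.
#' @examples
#' ens <- simulate_kmc(chcry4_rates(), t_max = 200, n_traj = 5, seed = 1)
#' ensemble_mean(ens)
#' @export
simulate_kmc <- function(rates, t_max = 1000, dt_sample = 1, n_traj = 51,
                         seed = 42, smooth_window = 0) {
  rates <- as_rate_constants(rates)
  if (t_max <= 0 || dt_sample <= 0 || n_traj < 1) {
    abort("t_max > 0, dt_sample > 0 and n_traj >= 1 are required")
  }
  times <- seq(0, t_max, by = dt_sample)
  k <- if (smooth_window > 0) max(1L, round(smooth_window / dt_sample)) else 1L

  traces <- purrr::map(seq_len(n_traj), function(i) {
    states <- kmc_trajectory(rates, t_max, times, trajectory_seed(seed, i))
    occ <- matrix(0, length(times), 4)
    occ[cbind(seq_along(times), states)] <- 1
    if (k > 1L) occ <- apply(occ, 2, running_mean, k = k)
    colnames(occ) <- OCC_COLS
    dplyr::bind_cols(tibble(sim_id = i, time_ps = times),
                     as_tibble(as.data.frame(occ)))
  })
  hop_ensemble(
    dplyr::bind_rows(traces),
    meta = list(generator = "kmc", rates = as.list(unclass(rates)),
                t_max = t_max, dt_sample = dt_sample, n_traj = n_traj,
                seed = seed, smooth_window = smooth_window)
  )
}

# one Gillespie trajectory; returns the state index at each grid time
kmc_trajectory <- function(rates, t_max, times, seed) {
  r <- unclass(rates)
  # per-state outgoing rates and destinations along the chain
  out_rates <- list(c(r[["kfAB"]]),
                    c(r[["kbAB"]], r[["kfBC"]]),
                    c(r[["kbBC"]], r[["kfCD"]]),
                    c(r[["kbCD"]]))
  out_dest <- list(2L, c(1L, 3L), c(2L, 4L), 3L)
  restore <- local_rng(seed)
  on.exit(restore())

  jump_t <- 0
  jump_s <- 1L
  t_now <- 0
  s_now <- 1L
  repeat {
    rs <- out_rates[[s_now]]
    total <- sum(rs)
    if (total <= 0) break
    t_now <- t_now + stats::rexp(1, total)
    if (t_now > t_max) break
    s_now <- if (length(rs) == 1L) {
      out_dest[[s_now]]
    } else {
      out_dest[[s_now]][1L + (stats::runif(1) * total >= rs[1])]
    }
    jump_t <- c(jump_t, t_now)
    jump_s <- c(jump_s, s_now)
  }
  jump_s[findInterval(times, jump_t)]
}

#' Pointwise ensemble mean of occupation traces
#'
#' @param ensemble A `hop_ensemble` or tidy occupation tibble.
#' @param subset Optional vector of `sim_id`s to average over.
#' @return A single-trace tibble (`time_ps`, `occ_A..occ_D`) with the
#'   arithmetic mean occupation at each time point.
#' @export
ensemble_mean <- function(ensemble, subset = NULL) {
  occ <- as_occupations(ensemble)
  if (!is.null(subset)) {
    if (length(subset) == 0) abort("subset must select at least one trace")
    unknown <- setdiff(subset, unique(occ$sim_id))
    if (length(unknown) > 0) {
      abort(paste("unknown sim_id(s):", paste(unknown, collapse = ", ")))
    }
    occ <- filter(occ, .data$sim_id %in% subset)
  }
  if (nrow(occ) == 0) abort("no traces to average")
  occ |>
    group_by(.data$time_ps) |>
    summarise(across(all_of(OCC_COLS), mean), .groups = "drop") |>
    arrange(.data$time_ps)
}

#' Add clipped Gaussian observation noise to a trace
#'
#' Adds independent zero-mean Gaussian noise (sd `sigma`) to every
#' site/time occupation, clips to `[0, 1]` and renormalises each time
#' point to sum to 1. Emulates the fluctuation of quantum populations
#' about their kinetic mean. `sigma = 0` returns the input unchanged.
#'
#' @param trace Occupation tibble (`time_ps`, `occ_A..occ_D`).
#' @param sigma Noise standard deviation (dimensionless occupation units).
#' @param seed RNG seed.
#' @return The noisy trace; every time point sums to 1 within 1e-9.
#' @export
add_observation_noise <- function(trace, sigma, seed = 1) {
  if (sigma < 0) abort("sigma must be >= 0")
  trace <- as_tibble(trace)
  if (sigma == 0) return(trace)
  occ <- as.matrix(trace[OCC_COLS])
  restore <- local_rng(seed)
  on.exit(restore())
  occ <- occ + matrix(stats::rnorm(length(occ), 0, sigma), nrow(occ))
  occ <- pmin(pmax(occ, 0), 1)
  s <- rowSums(occ)
  degenerate <- s < 1e-12
  occ[degenerate, ] <- 0.25
  s[degenerate] <- 1
  occ <- occ / s
  trace[OCC_COLS] <- as_tibble(as.data.frame(occ))
  trace
}

#' Labelled completed/stuck mixture ensemble
#'
#' Generates a two-subpopulation KMC ensemble emulating the observed split
#' of QM/MM trajectories: `n_completed` trajectories run with the full
#' rate set, `n_stuck` with a rate set whose forward B->C rate is zero, so
#' the hole stays confined to \{A, B\}. Ground-truth labels are attached
#' for downstream classifier validation. Because the labels describe the
#' observed phenotype, "completed" trajectories are sampled conditional on
#' the transfer actually completing (a realisation that never leaves
#' \{A, B\} within `t_max` is redrawn from a fresh substream).
#'
#' @param rates_completed Rate set for the completed subpopulation
#'   (default [chcry4_rates()]).
#' @param rates_stuck Rate set for the stuck subpopulation (default:
#'   `rates_completed` with `kfBC = 0`).
#' @param n_completed,n_stuck Subpopulation sizes (defaults 23 and 28, the
#'   reported ChCry4 split of 51 trajectories).
#' @param t_max,dt_sample Grid, as in [simulate_kmc()].
#' @param sigma Observation noise added per trace (default 0).
#' @param seed Master seed.
#' @param smooth_window Sliding-window width in ps (see [simulate_kmc()]).
#' @param threshold Completion criterion used for the conditional
#'   resampling (occupation on C or D, default 0.3).
#' @param max_redraw Attempt cap per completed trajectory.
#' @return A labelled `hop_ensemble` (labels `"completed"`/`"stuck"`).
#' @export
make_heterogeneous_ensemble <- function(rates_completed = chcry4_rates(),
                                        rates_stuck = NULL,
                                        n_completed = 23, n_stuck = 28,
                                        t_max = 1000, dt_sample = 1,
                                        sigma = 0, seed = 42,
                                        smooth_window = 0,
                                        threshold = 0.3,
                                        max_redraw = 1000) {
  if (n_completed + n_stuck < 1) abort("at least one trajectory required")
  rates_completed <- as_rate_constants(rates_completed)
  if (is.null(rates_stuck)) {
    rs <- unclass(rates_completed)
    rs[["kfBC"]] <- 0
    rates_stuck <- as_rate_constants(rs)
  } else {
    rates_stuck <- as_rate_constants(rates_stuck)
  }
  times <- seq(0, t_max, by = dt_sample)
  k <- if (smooth_window > 0) max(1L, round(smooth_window / dt_sample)) else 1L

  build_trace <- function(states, id) {
    occ <- matrix(0, length(times), 4)
    occ[cbind(seq_along(times), states)] <- 1
    if (k > 1L) occ <- apply(occ, 2, running_mean, k = k)
    colnames(occ) <- OCC_COLS
    dplyr::bind_cols(tibble(sim_id = id, time_ps = times),
                     as_tibble(as.data.frame(occ)))
  }

  traces <- vector("list", n_completed + n_stuck)
  id <- 0L
  for (i in seq_len(n_completed)) {
    id <- id + 1L
    attempt <- 0L
    repeat {
      sub_seed <- trajectory_seed(seed, id + attempt * 100003L)
      states <- kmc_trajectory(rates_completed, t_max, times, sub_seed)
      if (any(states >= 3L)) break
      attempt <- attempt + 1L
      if (attempt >= max_redraw) {
        abort("failed to draw a completing trajectory; rates too slow?")
      }
    }
    traces[[id]] <- build_trace(states, id)
  }
  for (i in seq_len(n_stuck)) {
    id <- id + 1L
    states <- kmc_trajectory(rates_stuck, t_max, times,
                             trajectory_seed(seed, id))
    traces[[id]] <- build_trace(states, id)
  }

  occ <- dplyr::bind_rows(traces)
  if (sigma > 0) {
    occ <- occ |> group_by(.data$sim_id) |>
      dplyr::group_modify(function(tr, key) {
        add_observation_noise(tr, sigma,
                              seed = trajectory_seed(seed + 1L, key$sim_id))
      }) |>
      ungroup() |>
      select(all_of(c("sim_id", "time_ps", OCC_COLS)))
  }
  labels <- tibble(
    sim_id = seq_len(n_completed + n_stuck),
    label = rep(c("completed", "stuck"), c(n_completed, n_stuck))
  )
  hop_ensemble(
    occ, labels = labels,
    meta = list(generator = "heterogeneous_kmc",
                rates_completed = as.list(unclass(rates_completed)),
                rates_stuck = as.list(unclass(rates_stuck)),
                n_completed = n_completed, n_stuck = n_stuck,
                t_max = t_max, dt_sample = dt_sample, sigma = sigma,
                seed = seed, smooth_window = smooth_window,
                threshold = threshold)
  )
}

# series columns understood by the site/coupling generator
SITE_SERIES_NAMES <- c("eps_A", "eps_B", "eps_C", "eps_D")
COUPLING_NAMES <- c("T_AB", "T_BC", "T_CD")

#' Ornstein-Uhlenbeck site-energy / coupling series
#'
#' Generates stationary mean-reverting series shaped like per-frame site
#' energies or neighbouring-pair electronic couplings: each requested
#' series fluctuates around its given mean (eV) with stationary standard
#' deviation `sd` and exponential autocorrelation time
#' `correlation_time`. Couplings exist only for the neighbouring pairs
#' (A,B), (B,C), (C,D); requesting any other pair is an error, reflecting
#' the chain topology where non-neighbour couplings vanish.
#'
#' @param means Named numeric vector of series means in eV; names from
#'   `eps_A..eps_D` (site energies) or `T_AB, T_BC, T_CD` (couplings).
#' @param sd Stationary standard deviation (eV), `>= 0`.
#' @param correlation_time Autocorrelation time in ps, `> 0`.
#' @param times Sampling grid in ps.
#' @param seed RNG seed.
#' @return Tibble with `time_ps` and one column per requested series.
#' @export
simulate_site_series <- function(means, sd, correlation_time, times,
                                 seed = 1) {
  if (sd < 0) abort("sd must be >= 0")
  if (correlation_time <= 0) abort("correlation_time must be > 0")
  validate_times(times)
  allowed <- c(SITE_SERIES_NAMES, COUPLING_NAMES)
  bad <- setdiff(names(means), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown or non-neighbour series: ",
                 paste(bad, collapse = ", "),
                 " (couplings exist only for AB, BC, CD)"))
  }
  restore <- local_rng(seed)
  on.exit(restore())
  n <- length(times)
  decay <- exp(-diff(times) / correlation_time)
  out <- purrr::map(as.list(means), function(mu) {
    if (sd == 0) return(rep(mu, n))
    x <- numeric(n)
    x[1] <- stats::rnorm(1, mu, sd)
    innov_sd <- sd * sqrt(1 - decay^2)
    z <- stats::rnorm(n - 1)
    for (i in seq_len(n - 1)) {
      x[i + 1] <- mu + (x[i] - mu) * decay[i] + innov_sd[i] * z[i]
    }
    x
  })
  dplyr::bind_cols(tibble(time_ps = as.numeric(times)), as_tibble(out))
}
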