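# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the ODE oracle is a fixed-step RK4
# integrator, the geometry oracles are double-loop brute force.

# published ChCry4 time constants (ps): forward 23, 149, 57; backward
# 141, 82, 240
REF_TAU <- c(tau_fAB = 23, tau_bAB = 141, tau_fBC = 149,
             tau_bBC = 82, tau_fCD = 57, tau_bCD = 240)
ref_rates <- function() do.call(rates_from_tau, as.list(REF_TAU))

# classical fixed-step RK4 for the linear system dp/dt = M p. For a
# constant matrix the four stages collapse exactly to one step matrix
# R = I + hM + (hM)^2/2 + (hM)^3/6 + (hM)^4/24, applied sequentially.
rk4_occupations <- function(rates, times, dt = 0.01, p0 = c(1, 0, 0, 0)) {
  M <- build_generator(rates)
  H <- M * dt
  R <- diag(4) + H + H %*% H / 2 + H %*% H %*% H / 6 +
    H %*% H %*% H %*% H / 24
  out <- matrix(NA_real_, length(times), 4)
  p <- p0
  t_now <- 0
  for (i in seq_along(times)) {
    n_steps <- round((times[i] - t_now) / dt)
    for (s in seq_len(n_steps)) p <- R %*% p
    t_now <- t_now + n_steps * dt
    out[i, ] <- p
  }
  colnames(out) <- c("occ_A", "occ_B", "occ_C", "occ_D")
  out
}

# draw a random rate set with time constants log-uniform in [lo, hi] ps
random_rates <- function(lo = 5, hi = 500) {
  tv <- exp(runif(6, log(lo), log(hi)))
  do.call(rates_from_tau, as.list(tv))
}

# brute-force all-pairs water count: residue heavy atoms vs any water atom
brute_water_count <- function(frames, f, res_number, cutoff = 5) {
  fr <- frames[frames$frame == f, ]
  res <- fr[fr$res_number == res_number & !fr$is_water &
              toupper(fr$element) != "H", ]
  waters <- fr[fr$is_water, ]
  count <- 0L
  for (wr in unique(waters$res_number)) {
    w <- waters[waters$res_number == wr, ]
    found <- FALSE
    for (i in seq_len(nrow(w))) {
      for (j in seq_len(nrow(res))) {
        d <- sqrt((w$x[i] - res$x[j])^2 + (w$y[i] - res$y[j])^2 +
                    (w$z[i] - res$z[j])^2)
        if (d <= cutoff + 1e-12) found <- TRUE
      }
    }
    if (found) count <- count + 1L
  }
  count
}

# brute-force minimum side-chain heavy-atom distance
brute_edge <- function(frames, f, res_a, res_b) {
  fr <- frames[frames$frame == f, ]
  backbone <- c("N", "CA", "C", "O", "OXT")
  pick <- function(rn) {
    fr[fr$res_number == rn & !fr$is_water & toupper(fr$element) != "H" &
         !fr$atom_name %in% backbone, ]
  }
  a <- pick(res_a)
  b <- pick(res_b)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

occ_matrix <- function(trace) {
  as.matrix(trace[, c("occ_A", "occ_B", "occ_C", "occ_D")])
}
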