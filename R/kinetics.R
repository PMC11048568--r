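#' Generator matrix of the four-state hole-transfer master equation
#'
#' Builds the 4x4 rate matrix M of the linear master equation
#' `dp/dt = M p` for the reversible chain A <-> B <-> C <-> D, with
#' `p = (A, B, C, D)` the state occupations. Only nearest-neighbour
#' entries are non-zero and every column sums to zero, so total occupation
#' is conserved.
#'
#' @param rates A `rate_constants` object (1/ps).
#' @return A 4x4 numeric matrix (1/ps) with dimnames A-D.
#' @examples
#' build_generator(chcry4_rates())
#' @export
build_generator <- function(rates) {
  r <- unclass(as_rate_constants(rates))
  M <- matrix(0, 4, 4, dimnames = list(SITE_LABELS, SITE_LABELS))
  M[1, 1] <- -r[["kfAB"]]
  M[1, 2] <- r[["kbAB"]]
  M[2, 1] <- r[["kfAB"]]
  M[2, 2] <- -(r[["kbAB"]] + r[["kfBC"]])
  M[2, 3] <- r[["kbBC"]]
  M[3, 2] <- r[["kfBC"]]
  M[3, 3] <- -(r[["kbBC"]] + r[["kfCD"]])
  M[3, 4] <- r[["kbCD"]]
  M[4, 3] <- r[["kfCD"]]
  M[4, 4] <- -r[["kbCD"]]
  M
}

validate_p0 <- function(p0) {
  if (length(p0) != 4L || !is.numeric(p0) || any(!is.finite(p0))) {
    abort("p0 must be four finite numeric values")
  }
  if (any(p0 < 0)) abort("p0 must be non-negative")
  if (abs(sum(p0) - 1) > 1e-9) {
    abort("p0 must sum to 1 within 1e-9")
  }
  invisible(p0)
}

validate_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times))) {
    abort("times must be a finite numeric grid")
  }
  if (times[1] != 0) abort("time grid must start at 0 ps")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    abort("time grid must be strictly increasing")
  }
  invisible(times)
}

#' Propagate the four-state master equation
#'
#' Computes the exact solution of `dp/dt = M p` at the requested times via
#' eigendecomposition of the generator. The chain generator is similar to a
#' symmetric tridiagonal matrix whenever all off-diagonal rates are
#' positive, so its eigensystem is real; degenerate generators fall back
#' first to exact matrix-exponential stepping (`Matrix::expm`) and, should
#' that fail, to a stiff dense integrator (`deSolve::lsoda`, rtol 1e-10,
#' atol 1e-12).
#'
#' @param rates A `rate_constants` object.
#' @param times Sampling grid in ps: strictly increasing, starting at 0.
#' @param p0 Initial occupation vector; defaults to a hole on TrpA,
#'   `(1, 0, 0, 0)`, i.e. the state after the first FAD <- TrpA electron
#'   transfer has completed.
#' @return A tibble with columns `time_ps, occ_A, occ_B, occ_C, occ_D`.
#'   Occupations lie in `[0, 1]` and sum to 1 within 1e-9 at every time.
#' @examples
#' propagate(chcry4_rates(), times = 0:1000)
#' @export
propagate <- function(rates, times, p0 = c(1, 0, 0, 0)) {
  rates <- as_rate_constants(rates)
  validate_p0(p0)
  validate_times(times)
  M <- build_generator(rates)

  P <- tryCatch(propagate_eigen(M, p0, times),
                error = function(e) NULL)
  if (is.null(P)) {
    P <- tryCatch(propagate_expm(M, p0, times),
                  error = function(e) NULL)
  }
  if (is.null(P)) P <- propagate_lsoda(M, p0, times)

  # clamp numerical noise at the [0, 1] boundaries
  P[P < 0 & P > -1e-9] <- 0
  P[P > 1 & P < 1 + 1e-9] <- 1
  tibble(time_ps = as.numeric(times),
         occ_A = P[1, ], occ_B = P[2, ], occ_C = P[3, ], occ_D = P[4, ])
}

propagate_eigen <- function(M, p0, times) {
  ev <- eigen(M)
  if (any(abs(Im(ev$values)) > 1e-10)) stop("complex eigensystem")
  V <- Re(ev$vectors)
  lambda <- Re(ev$values)
  if (rcond(V) < 1e-10) stop("ill-conditioned eigenvector matrix")
  coef <- solve(V, p0)
  # p(t) = V diag(exp(lambda t)) V^-1 p0, vectorised over the grid
  E <- exp(outer(lambda, times))        # 4 x T
  V %*% (coef * E)
}

# stepping with the exact matrix exponential per (cached) grid increment;
# handles defective generators that the eigendecomposition rejects
propagate_expm <- function(M, p0, times) {
  out <- matrix(0, 4, length(times))
  p <- p0
  if (times[1] > 0) p <- as.vector(Matrix::expm(M * times[1]) %*% p)
  out[, 1] <- p
  dts <- diff(times)
  if (length(dts) > 0) {
    keys <- as.character(signif(dts, 12))
    steps <- lapply(stats::setNames(nm = unique(keys)), function(k) {
      as.matrix(Matrix::expm(M * dts[match(k, keys)]))
    })
    for (i in seq_along(dts)) {
      p <- as.vector(steps[[keys[i]]] %*% p)
      out[, i + 1] <- p
    }
  }
  if (any(!is.finite(out))) stop("non-finite matrix-exponential propagation")
  out
}

propagate_lsoda <- function(M, p0, times) {
  tgrid <- times
  if (length(tgrid) == 1L) tgrid <- c(0, tgrid)
  sol <- suppressWarnings(deSolve::lsoda(
    y = p0, times = tgrid,
    func = function(t, y, parms) list(as.vector(M %*% y)),
    rtol = 1e-10, atol = 1e-12
  ))
  if (nrow(sol) < length(tgrid)) {
    abort("stiff integrator failed to reach the end of the time grid")
  }
  out <- t(sol[, -1, drop = FALSE])
  if (length(times) == 1L) out <- out[, ncol(out), drop = FALSE]
  out
}

#' Equilibrium occupations of the reversible chain
#'
#' For a fully reversible chain the long-time limit of the master equation
#' has the closed form `(1, K1, K1 K2, K1 K2 K3) / Z` with
#' `K1 = kfAB/kbAB`, `K2 = kfBC/kbBC`, `K3 = kfCD/kbCD`. This is the
#' normalised null vector of the generator and satisfies detailed balance.
#'
#' @param rates A `rate_constants` object; all six rates must be strictly
#'   positive (an irreversible chain has an absorbing end; propagate to
#'   large t instead).
#' @return Named numeric occupation vector (A, B, C, D) summing to 1.
#' @examples
#' steady_state(chcry4_rates())
#' @export
steady_state <- function(rates) {
  r <- unclass(as_rate_constants(rates))
  if (any(r == 0)) {
    abort(paste("steady_state requires all six rates > 0;",
                "for an irreversible chain use propagate() at large t"))
  }
  K1 <- r[["kfAB"]] / r[["kbAB"]]
  K2 <- r[["kfBC"]] / r[["kbBC"]]
  K3 <- r[["kfCD"]] / r[["kbCD"]]
  p <- c(A = 1, B = K1, C = K1 * K2, D = K1 * K2 * K3)
  p / sum(p)
}

#' Validate and normalise an occupation trace
#'
#' Checks the occupation-table contract: a `time_ps` grid that is strictly
#' increasing from 0 and four site columns `occ_A..occ_D` in `[0, 1]`.
#' Raw quantum populations are only approximately normalised, so per-time
#' sums deviating from 1 by at most `max_dev` are renormalised (with a
#' warning); larger deviations are an error.
#'
#' @param trace Data frame with `time_ps` and `occ_A..occ_D`.
#' @param max_dev Largest tolerated deviation of a per-time occupation sum
#'   from 1 before renormalisation is refused (default 0.05).
#' @param quiet Suppress the renormalisation warning.
#' @return The trace as a tibble with every row renormalised to sum to 1.
#' @export
validate_trace <- function(trace, max_dev = 0.05, quiet = FALSE) {
  trace <- as_tibble(trace)
  need <- c("time_ps", OCC_COLS)
  missing <- setdiff(need, names(trace))
  if (length(missing) > 0) {
    abort(paste("occupation table lacks column(s):",
                paste(missing, collapse = ", ")))
  }
  validate_times(trace$time_ps)
  occ <- as.matrix(trace[OCC_COLS])
  if (any(!is.finite(occ))) abort("occupations must be finite")
  if (any(occ < -max_dev) || any(occ > 1 + max_dev)) {
    abort("occupations outside [0, 1] beyond the permitted tolerance")
  }
  s <- rowSums(occ)
  dev <- max(abs(s - 1))
  if (dev > max_dev) {
    abort(sprintf(
      "occupation sums deviate from 1 by %.3g (> %.3g); not renormalising",
      dev, max_dev))
  }
  if (dev > 1e-9) {
    if (!quiet) {
      warn(sprintf("renormalising occupation sums (max deviation %.3g)", dev))
    }
    occ <- pmin(pmax(occ, 0), 1)
    occ <- occ / rowSums(occ)
    trace[OCC_COLS] <- as_tibble(as.data.frame(occ))
  }
  trace
}
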