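#' Fit the six chain rate constants to an occupation trace
#'
#' Recovers the forward/backward rate constants of the reversible
#' A <-> B <-> C <-> D chain by least squares: the sum of squared residuals
#' between the observed occupations and the master-equation solution
#' started from `p0` is minimised over the six rates. Optimisation runs in
#' log time-constant space (positivity enforced by construction; the rates
#' span an order of magnitude) with Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) from `n_starts` seeded log-uniform starting
#' points with time constants in `[1, 1000]` ps. Residuals are equally
#' weighted across the four sites and all time points. Ties between equally
#' good optima are broken by the lexicographically smallest parameter
#' vector, so the result is deterministic for a given seed.
#'
#' @param trace Occupation table (`time_ps`, `occ_A..occ_D`) with at least
#'   20 time points; passed through [validate_trace()].
#' @param init Optional `rate_constants` used as the first start.
#' @param n_starts Number of multi-start initialisations (default 16).
#' @param seed Integer seed for the random starts.
#' @param p0 Initial occupation vector of the model (default hole on TrpA).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return A `kinetic_fit` object: `rates` (`rate_constants`), `tau_ps`,
#'   `residual_norm` (root of the summed squared residuals), `n_points`,
#'   `converged`, `per_parameter_spread` (standard deviation of each
#'   recovered rate across converged starts), and a `starts` tibble of all
#'   multi-start optima. If no start converges, `converged` is `FALSE` and
#'   the best optimum found is still returned.
#' @examples
#' tr <- propagate(chcry4_rates(), times = seq(0, 1000, 10))
#' fit <- fit_rates(tr, n_starts = 4, seed = 1)
#' tidy(fit)
#' @export
fit_rates <- function(trace, init = NULL, n_starts = 16, seed = 1,
                      p0 = c(1, 0, 0, 0), max_iter = 200) {
  trace <- validate_trace(trace, quiet = TRUE)
  if (nrow(trace) < 20L) {
    abort("fit_rates needs at least 20 time points")
  }
  if (n_starts < 1L) abort("n_starts must be >= 1")
  validate_p0(p0)

  times <- trace$time_ps
  obs <- as.matrix(trace[OCC_COLS])

  # residuals as a function of log time constants (ps); iterates are kept
  # inside a generous physical window to avoid degenerate generators
  resid_fn <- function(log_tau) {
    log_tau <- pmin(pmax(log_tau, log(1e-3)), log(1e7))
    r <- as_rate_constants(stats::setNames(exp(-log_tau), RATE_NAMES))
    pred <- propagate(r, times, p0 = p0)
    as.vector(as.matrix(pred[OCC_COLS]) - obs)
  }

  starts <- fit_starting_points(init, n_starts, seed)
  opt <- purrr::map(starts, function(th0) {
    fit1 <- tryCatch(
      minpack.lm::nls.lm(
        par = th0, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                             ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit1)) return(NULL)
    # report inside the same window the residual function evaluates
    list(par = pmin(pmax(fit1$par, log(1e-3)), log(1e7)),
         ssr = fit1$deviance,
         converged = fit1$info %in% 1:4)
  })
  opt <- opt[!vapply(opt, is.null, logical(1))]
  if (length(opt) == 0) abort("all optimisation starts failed")

  starts_tbl <- tibble(
    start = seq_along(opt),
    residual_norm = sqrt(vapply(opt, `[[`, numeric(1), "ssr")),
    converged = vapply(opt, `[[`, logical(1), "converged")
  )
  pars <- do.call(rbind, lapply(opt, function(o) exp(-o$par)))
  colnames(pars) <- RATE_NAMES
  starts_tbl <- dplyr::bind_cols(starts_tbl, as_tibble(as.data.frame(pars)))

  best <- pick_best_start(starts_tbl)
  rates <- as_rate_constants(unlist(best[RATE_NAMES]))

  conv <- starts_tbl$converged
  spread <- if (sum(conv) >= 2) {
    apply(pars[conv, , drop = FALSE], 2, stats::sd)
  } else {
    stats::setNames(rep(NA_real_, 6), RATE_NAMES)
  }

  structure(
    list(
      rates = rates,
      tau_ps = tau(rates),
      residual_norm = best$residual_norm,
      n_points = nrow(trace),
      converged = any(conv),
      per_parameter_spread = spread,
      starts = starts_tbl,
      p0 = p0,
      data = trace
    ),
    class = "kinetic_fit"
  )
}

# log time-constant starting points: the supplied init first (if any),
# the remainder log-uniform in [1, 1000] ps
fit_starting_points <- function(init, n_starts, seed) {
  starts <- list()
  if (!is.null(init)) {
    starts <- list(log(tau(as_rate_constants(init))))
    names(starts[[1]]) <- NULL
  }
  n_random <- n_starts - length(starts)
  if (n_random > 0) {
    rng <- local_rng(seed)
    on.exit(rng())
    for (i in seq_len(n_random)) {
      starts <- c(starts, list(stats::runif(6, log(1), log(1000))))
    }
  }
  starts
}

# lowest residual norm; ties (within 1e-12 relative) broken by the
# lexicographically smallest parameter vector
pick_best_start <- function(starts_tbl) {
  rn <- starts_tbl$residual_norm
  tol <- max(1e-15, 1e-12 * (1 + min(rn)))
  cand <- which(rn <= min(rn) + tol)
  if (length(cand) > 1) {
    mat <- as.matrix(starts_tbl[cand, RATE_NAMES])
    ord <- do.call(order, as.data.frame(mat))
    cand <- cand[ord[1]]
  }
  starts_tbl[cand[1], ]
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> four-state reversible chain, least-squares fit\n")
  cat(sprintf("  %d time points, residual norm %.4g, converged: %s\n",
              x$n_points, x$residual_norm, x$converged))
  df <- data.frame(rate_per_ps = as.numeric(unclass(x$rates)),
                   tau_ps = as.numeric(x$tau_ps),
                   row.names = RATE_NAMES)
  print(df, digits = 4)
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return One row per rate constant: `term`, `rate_per_ps`, `tau_ps`, and
#'   `spread` (multi-start dispersion of the rate, 1/ps).
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(
    term = RATE_NAMES,
    rate_per_ps = as.numeric(unclass(x$rates)),
    tau_ps = as.numeric(x$tau_ps),
    spread = as.numeric(x$per_parameter_spread)
  )
}

#' One-row fit summary
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A tibble with `residual_norm`, `n_points`, `n_starts`,
#'   `n_converged`, `converged`.
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(
    residual_norm = x$residual_norm,
    n_points = x$n_points,
    n_starts = nrow(x$starts),
    n_converged = sum(x$starts$converged),
    converged = x$converged
  )
}

#' Fitted occupation curves of a kinetic fit
#'
#' @param object A `kinetic_fit`.
#' @param times Optional grid in ps; defaults to the fitted data's grid.
#' @param ... Unused.
#' @return A tibble of model occupations on the grid.
#' @export
fitted_occupations <- function(object, times = NULL, ...) {
  times <- times %||% object$data$time_ps
  propagate(object$rates, times, p0 = object$p0)
}

#' Plot observed occupations with fitted curves
#'
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot: per-site observed points and model curves vs time.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  obs <- pivot_occ(object$data) |> mutate(kind = "observed")
  fit <- pivot_occ(fitted_occupations(object)) |> mutate(kind = "fitted")
  ggplot2::ggplot(NULL, ggplot2::aes(x = .data$time_ps, y = .data$occupation,
                                     colour = .data$site)) +
    ggplot2::geom_point(data = obs, size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = fit, linewidth = 0.8) +
    ggplot2::labs(x = "time (ps)", y = "occupation",
                  title = "Hole occupations and kinetic-model fit") +
    ggplot2::theme_minimal()
}

# long form of an occupation table
pivot_occ <- function(trace) {
  tidyr::pivot_longer(trace, all_of(OCC_COLS),
                      names_to = "site", names_prefix = "occ_",
                      values_to = "occupation")
}
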