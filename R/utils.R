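#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Seed the RNG locally: returns a restore function for on.exit().
local_rng <- function(seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    function() {
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }
  } else {
    function() invisible(NULL)
  }
}

# Independent per-trajectory seed derived from a master seed, so that
# growing n_traj never reshuffles earlier trajectories. Kept < 2^31.
trajectory_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 100000) * 20011 + i)
}

# centred running mean with partial windows at the edges; k in samples
running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
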