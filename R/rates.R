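#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across all_of left_join bind_rows n
NULL

# Canonical ordering of the six rate constants of the reversible
# A <-> B <-> C <-> D hole-transfer chain.
RATE_NAMES <- c("kfAB", "kbAB", "kfBC", "kbBC", "kfCD", "kbCD")

# Occupation column names used throughout the package.
OCC_COLS <- c("occ_A", "occ_B", "occ_C", "occ_D")
SITE_LABELS <- c("A", "B", "C", "D")

#' Construct the six rate constants of the tryptophan-tetrad chain
#'
#' The hole-transfer chain TrpA <-> TrpB <-> TrpC <-> TrpD is parameterised
#' by six first-order rate constants: a forward (`kf`) and a backward (`kb`)
#' rate for each neighbouring pair. All rates are in 1/ps and must be finite
#' and non-negative.
#'
#' @param kfAB,kbAB,kfBC,kbBC,kfCD,kbCD Rate constants in 1/ps.
#' @return An object of class `rate_constants`: a named numeric vector of
#'   length six in the canonical order `kfAB, kbAB, kfBC, kbBC, kfCD, kbCD`.
#' @seealso [rates_from_tau()] to build from time constants in ps,
#'   [chcry4_rates()] for the published herring-Cry4 values, [tau()] for the
#'   reciprocal (time-constant) view.
#' @examples
#' r <- rate_constants(1 / 23, 1 / 141, 1 / 149, 1 / 82, 1 / 57, 1 / 240)
#' tau(r)
#' @export
rate_constants <- function(kfAB, kbAB, kfBC, kbBC, kfCD, kbCD) {
  x <- c(kfAB = kfAB, kbAB = kbAB, kfBC = kfBC, kbBC = kbBC,
         kfCD = kfCD, kbCD = kbCD)
  validate_rates(x)
  structure(x, class = "rate_constants")
}

#' Coerce a named vector or list to rate constants
#'
#' @param x Named numeric vector or list carrying the six canonical names.
#' @return A `rate_constants` object.
#' @export
as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) {
    validate_rates(unclass(x))
    return(x)
  }
  x <- unlist(x)
  if (!all(RATE_NAMES %in% names(x))) {
    abort(paste0("rate constants need names ",
                 paste(RATE_NAMES, collapse = ", ")))
  }
  do.call(rate_constants, as.list(x[RATE_NAMES]))
}

validate_rates <- function(x) {
  if (length(x) != 6L || !is.numeric(x)) {
    abort("rate constants must be six numeric values")
  }
  if (any(!is.finite(x))) abort("rate constants must be finite")
  if (any(x < 0)) abort("rate constants must be non-negative")
  invisible(x)
}

#' Time constants (ps) of a rate-constant set
#'
#' The reciprocal view of the rates: `tau = 1/k` in ps. A zero rate maps to
#' an infinite time constant. For strictly positive rates the mapping is a
#' bijection, inverted by [rates_from_tau()].
#'
#' @param rates A `rate_constants` object.
#' @return Named numeric vector `tau_fAB, tau_bAB, tau_fBC, tau_bBC,
#'   tau_fCD, tau_bCD` in ps.
#' @export
tau <- function(rates) {
  rates <- as_rate_constants(rates)
  out <- 1 / unclass(rates)
  names(out) <- sub("^k", "tau_", RATE_NAMES)
  out
}

#' Build rate constants from time constants in ps
#'
#' @param tau_fAB,tau_bAB,tau_fBC,tau_bBC,tau_fCD,tau_bCD Time constants in
#'   ps; each must be strictly positive (use `Inf` for a vanishing rate).
#' @return A `rate_constants` object with `k = 1/tau` in 1/ps.
#' @examples
#' rates_from_tau(23, 141, 149, 82, 57, 240)
#' @export
rates_from_tau <- function(tau_fAB, tau_bAB, tau_fBC, tau_bBC,
                           tau_fCD, tau_bCD) {
  tv <- c(tau_fAB, tau_bAB, tau_fBC, tau_bBC, tau_fCD, tau_bCD)
  if (any(is.na(tv)) || any(tv <= 0)) {
    abort("time constants must be strictly positive (Inf allowed)")
  }
  do.call(rate_constants, as.list(1 / tv))
}

#' Published ChCry4 hole-transfer rate constants
#'
#' The six rate constants reported for Atlantic herring cryptochrome 4,
#' entered as time constants and inverted: forward 23, 149, 57 ps and
#' backward 141, 82, 240 ps for the A-B, B-C and C-D steps respectively.
#'
#' @return A `rate_constants` object.
#' @export
chcry4_rates <- function() {
  rates_from_tau(23, 141, 149, 82, 57, 240)
}

#' Residue numbering of the ChCry4 tryptophan tetrad
#'
#' @return A tibble mapping the chain labels A-D to ChCry4 residue numbers
#'   (396, 373, 319, 370).
#' @export
trp_sites <- function() {
  tibble(site = SITE_LABELS,
         residue_number = c(396L, 373L, 319L, 370L))
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants> six-rate reversible chain A <-> B <-> C <-> D\n")
  df <- data.frame(
    transition = c("A->B", "B->A", "B->C", "C->B", "C->D", "D->C"),
    rate_per_ps = unclass(x),
    tau_ps = 1 / unclass(x),
    row.names = RATE_NAMES
  )
  print(df, digits = 4)
  invisible(x)
}

#' Tidy a rate-constant set
#'
#' @param x A `rate_constants` object.
#' @param ... Unused.
#' @return A tibble with one row per transition: `term`, `pair`,
#'   `direction`, `rate_per_ps`, `tau_ps`.
#' @method tidy rate_constants
#' @export
tidy.rate_constants <- function(x, ...) {
  tibble(
    term = RATE_NAMES,
    pair = rep(c("AB", "BC", "CD"), each = 2),
    direction = rep(c("forward", "backward"), 3),
    rate_per_ps = as.numeric(unclass(x)),
    tau_ps = 1 / as.numeric(unclass(x))
  )
}

#' Write rate constants to JSON
#'
#' Serialises the six rates (1/ps) as top-level keys plus a mirrored
#' `tau_ps` block of time constants in ps.
#'
#' @param rates A `rate_constants` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rates_json <- function(rates, path) {
  rates <- as_rate_constants(rates)
  obj <- as.list(unclass(rates))
  obj$tau_ps <- as.list(tau(rates))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read rate constants from JSON
#'
#' @param path File written by [write_rates_json()] (only the six top-level
#'   rate keys are required).
#' @return A `rate_constants` object.
#' @export
read_rates_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_rate_constants(obj[RATE_NAMES])
}
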