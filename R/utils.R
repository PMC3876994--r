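# Shared internals: the simulation window, rounding, seed scoping.

# Simulation window used throughout: calendar years 2000-2100 inclusive.
sim_years <- function() 2000:2100
n_sim_years <- function() 101L

#' Round half away from zero
#'
#' Commercial rounding used when reporting monetary tables: 0.5 always rounds
#' away from zero, unlike [round()]'s round-half-even. Internal math is kept
#' at full precision; this is applied only at the reporting boundary.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (0 for whole dollars/millions).
#' @return `x` rounded half away from zero to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), inherits = FALSE))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stopf("%s must lie in [0, 1]", what)
  }
  invisible(x)
}
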