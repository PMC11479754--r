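# Internal helpers shared across the package.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' that seeded operations are pure functions of (inputs, seed) and do not
#' perturb the global random stream. A `NULL` seed evaluates `code` under the
#' current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Validate a vector of observed lifespans: integer-valued days >= 1.
check_lifespans <- function(lifespans, arg = "lifespans") {
  if (length(lifespans) == 0L)
    stop(sprintf("'%s' is empty: at least one observed lifespan is required", arg))
  if (!is.numeric(lifespans) || anyNA(lifespans) || any(!is.finite(lifespans)))
    stop(sprintf("'%s' must be finite numeric days", arg))
  if (any(lifespans < 1))
    stop(sprintf("'%s' must be >= 1 day (deaths are recorded from day 1)", arg))
  if (any(abs(lifespans - round(lifespans)) > 1e-8))
    stop(sprintf("'%s' must be integer-valued (daily census)", arg))
  as.integer(round(lifespans))
}

# Interior points of a log-spaced grid on [lo, hi], used for multi-start fits.
log_grid <- function(lo, hi, k) {
  10^(seq(log10(lo), log10(hi), length.out = k + 2L)[seq_len(k) + 1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
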