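#' Configuration for a synthetic two-group duckweed-style cohort
#'
#' Defines the study conditions emulated by the generator: two offspring
#' groups (by default "first" and "fifth", i.e. offspring of young vs old
#' parents) of 191 and 192 individuals, logistic mortality with a 10-fold
#' distinct initial-mortality parameter and common rate and heterogeneity
#' parameters, a group-dependent integer age at first reproduction (AFR,
#' mean 3.0 d vs 2.5 d), and Bernoulli daily reproduction after AFR with a
#' forced final-day birth so that every individual satisfies the
#' operational death definition (death = day the last offspring detached).
#'
#' The fecundity process is a stylized stand-in for duckweed's alternating
#' single-frond detachment (at most one offspring per day here), not an
#' estimate from data.
#'
#' @param n named integer vector of group sizes (names are the group
#'   labels; first element is the reference group).
#' @param params list of two [mortality_params()], one per group.
#' @param afr_mean per-group mean age at first reproduction (days); AFR is
#'   drawn as `1 + Binomial(4, (afr_mean - 1)/4)` and truncated at the
#'   lifespan.
#' @param repro_prob per-day probability of producing one offspring on days
#'   `[AFR, L - 1]` (day `L` always produces at least one).
#' @param seed integer seed from which all of the generator's randomness
#'   flows.
#' @return an object of class `cohort_config`.
#' @examples
#' cohort_config()
#' @export
cohort_config <- function(n = c(first = 191L, fifth = 192L),
                          params = list(
                            mortality_params("logistic", a = 1e-4, b = 0.3, c = 1),
                            mortality_params("logistic", a = 1e-3, b = 0.3, c = 1)),
                          afr_mean = c(3.0, 2.5),
                          repro_prob = 0.5,
                          seed = 1L) {
  if (length(n) != 2L || is.null(names(n)) || any(!nzchar(names(n))))
    stop("'n' must be a named length-2 vector of group sizes")
  if (any(n < 1)) stop("group sizes must be >= 1")
  stopifnot(length(params) == 2L,
            all(vapply(params, inherits, logical(1), "mortality_params")))
  if (length(afr_mean) != 2L || any(afr_mean < 1))
    stop("'afr_mean' must be two values >= 1 day")
  if (repro_prob <= 0 || repro_prob > 1)
    stop("'repro_prob' must be in (0, 1]")
  structure(list(n = as.integer(n), groups = names(n), params = params,
                 afr_mean = afr_mean, repro_prob = repro_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("synthetic cohort configuration\n")
  for (i in 1:2) {
    p <- x$params[[i]]
    cat(sprintf("  %s: n = %d, %s(a = %g%s%s), AFR mean %.2f d\n",
                x$groups[i], x$n[i], p$family, p$a,
                if (!is.null(p$b)) sprintf(", b = %g", p$b) else "",
                if (!is.null(p$c)) sprintf(", c = %g", p$c) else "",
                x$afr_mean[i]))
  }
  cat(sprintf("  daily reproduction probability %.2f, seed %d\n",
              x$repro_prob, x$seed))
  invisible(x)
}

#' Draw daily-censored lifespans from a mortality model
#'
#' Inverse-CDF sampling: a continuous death time `T` is obtained by
#' inverting the survival function at a uniform deviate, and the recorded
#' lifespan is the day index `L` with `T` in `[L, L + 1)`. Draws with
#' `T < 1` (death before the first census) are resampled; the fraction of
#' resampled draws is attached as attribute `"truncated_frac"`.
#'
#' @param n number of lifespans to draw.
#' @param params a [mortality_params()] object.
#' @param seed optional integer seed.
#' @return integer vector of `n` lifespans (days, all `>= 1`).
#' @examples
#' sample_lifespans(5, mortality_params("exponential", a = log(2)), seed = 1)
#' @export
sample_lifespans <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "mortality_params"), n >= 1)
  with_seed(seed, {
    L <- integer(n)
    need <- rep(TRUE, n)
    n_resampled <- 0L
    while (any(need)) {
      m <- sum(need)
      t_cont <- invert_survival(params, stats::runif(m))
      Lm <- as.integer(floor(t_cont))
      ok <- Lm >= 1L
      idx <- which(need)
      L[idx[ok]] <- Lm[ok]
      need[idx[ok]] <- FALSE
      n_resampled <- n_resampled + sum(!ok)
    }
    structure(L, truncated_frac = n_resampled / (n + n_resampled))
  })
}

# Continuous death time t with l(t) = u, per family.
invert_survival <- function(params, u) {
  a <- params$a; b <- params$b; cc <- params$c
  switch(params$family,
    exponential = -log(u) / a,
    gompertz    = log1p(-b * log(u) / a) / b,
    weibull     = (-log(u))^(1 / b) / a,
    logistic    = log1p(b * expm1(-cc * log(u)) / (a * cc)) / b)
}

#' Generate a synthetic two-group cohort of reproduction schedules
#'
#' For each individual: draw a lifespan from the group's mortality model
#' ([sample_lifespans()]); draw an integer AFR (truncated at the lifespan);
#' place Bernoulli offspring on each day in `[AFR, L - 1]`; and force at
#' least one offspring on day `L` so the operational death definition
#' holds. All randomness flows from the config seed.
#'
#' @param config a [cohort_config()].
#' @return a long-format cohort data frame (class `cohort`) with columns
#'   `individual_id`, `group`, `day`, `offspring_count`, one row per
#'   (individual, day). The config and the per-group fraction of resampled
#'   pre-day-1 deaths are attached as attributes `"config"` and
#'   `"truncated_frac"`.
#' @examples
#' coh <- generate_cohort(cohort_config(n = c(first = 5, fifth = 5), seed = 1))
#' head(coh)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    rows <- vector("list", sum(config$n))
    trunc_frac <- numeric(2)
    idx <- 0L
    for (g in 1:2) {
      L <- sample_lifespans(config$n[g], config$params[[g]])
      trunc_frac[g] <- attr(L, "truncated_frac")
      afr_p <- (config$afr_mean[g] - 1) / 4
      afr <- pmin(1L + stats::rbinom(config$n[g], 4L, afr_p), L)
      for (i in seq_len(config$n[g])) {
        idx <- idx + 1L
        m <- integer(L[i])
        if (afr[i] <= L[i] - 1L)
          m[afr[i]:(L[i] - 1L)] <-
            stats::rbinom(L[i] - afr[i], 1L, config$repro_prob)
        m[L[i]] <- max(1L, m[L[i]])
        rows[[idx]] <- data.frame(
          individual_id = sprintf("%s_%03d", config$groups[g], i),
          group = config$groups[g],
          day = seq_len(L[i]),
          offspring_count = m,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("cohort", "data.frame"),
              config = config,
              truncated_frac = stats::setNames(trunc_frac, config$groups))
  })
}
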