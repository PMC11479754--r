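#' Mortality model parameters
#'
#' Constructs and validates a parameter set for one of the four mortality
#' model families used throughout the package. The families share a common
#' parameter naming convention: `a` is the initial-mortality (level)
#' parameter, `b` the mortality-rate (shape) parameter, and `c` the
#' heterogeneity/deceleration parameter of the logistic family.
#'
#' The survival functions are, with age \eqn{t} in days:
#' \describe{
#'   \item{exponential}{\eqn{l(t) = \exp(-a t)}, constant hazard \eqn{a}.}
#'   \item{gompertz}{\eqn{l(t) = \exp(-(a/b)(e^{bt} - 1))}, hazard
#'     \eqn{a e^{bt}}.}
#'   \item{weibull}{\eqn{l(t) = \exp(-(a t)^b)}, hazard
#'     \eqn{a b (a t)^{b-1}}. This two-parameter form keeps `a` as the
#'     level-like scale parameter and `b` as the shape; it is a documented
#'     convention of this package (several Weibull parameterizations are in
#'     circulation).}
#'   \item{logistic}{\eqn{l(t) = (1 + (a c / b)(e^{bt} - 1))^{-1/c}},
#'     hazard \eqn{a e^{bt} / (1 + (a c / b)(e^{bt} - 1))}. As \eqn{c \to 0}
#'     it reduces to Gompertz; large `c` produces late-life mortality
#'     plateaus.}
#' }
#'
#' All rates are per day and all ages in days.
#'
#' @param family one of `"exponential"`, `"gompertz"`, `"weibull"`,
#'   `"logistic"`.
#' @param a initial-mortality parameter (> 0, per day).
#' @param b mortality-rate parameter (> 0, per day); required for all
#'   families except exponential.
#' @param c heterogeneity parameter (> 0, dimensionless); logistic only.
#' @return an object of class `mortality_params`: a list with elements
#'   `family`, `a`, `b`, `c` and the parameter count `k`.
#' @examples
#' mortality_params("logistic", a = 0.001, b = 0.25, c = 1)
#' @export
mortality_params <- function(family = c("exponential", "gompertz", "weibull",
                                        "logistic"),
                             a, b = NULL, c = NULL) {
  family <- match.arg(family)
  k <- model_n_params(family)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("parameter 'a' must be a single finite value > 0")
  if (k >= 2L) {
    if (is.null(b) || !is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
      stop(sprintf("parameter 'b' must be a single finite value > 0 for the %s family",
                   family))
  } else b <- NULL
  if (k == 3L) {
    if (is.null(c) || !is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
      stop("parameter 'c' must be a single finite value > 0 for the logistic family")
  } else c <- NULL
  structure(list(family = family, a = as.numeric(a),
                 b = if (!is.null(b)) as.numeric(b),
                 c = if (!is.null(c)) as.numeric(c),
                 k = k),
            class = "mortality_params")
}

#' @export
print.mortality_params <- function(x, ...) {
  vals <- unlist(x[c("a", "b", "c")])
  cat(sprintf("%s mortality parameters (k = %d):\n", x$family, x$k))
  print(signif(vals, 6))
  invisible(x)
}

# Number of free parameters per family.
model_n_params <- function(family) {
  switch(family, exponential = 1L, gompertz = 2L, weibull = 2L, logistic = 3L,
         stop("unknown model family: ", family))
}

# log survival, vectorized over t. Written with expm1/log1p so that the
# Gompertz (c -> 0) and exponential (b -> 0) limits are reached smoothly
# without catastrophic cancellation.
log_survival <- function(params, t) {
  a <- params$a; b <- params$b; cc <- params$c
  switch(params$family,
    exponential = -a * t,
    gompertz    = -(a / b) * expm1(b * t),
    weibull     = -(a * t)^b,
    logistic    = -log1p((a * cc / b) * expm1(b * t)) / cc)
}

#' Survival, hazard and daily death probability
#'
#' Closed-form evaluation of the survival function \eqn{l(t)}, the hazard
#' \eqn{h(t) = -d \ln l(t) / dt}, and the probability of death within a
#' one-day census interval for the four mortality families.
#'
#' An individual recorded with integer lifespan \eqn{L} is taken to have
#' died in the age interval \eqn{[L, L+1)}: death is detected on the day of
#' the last observed reproduction, so the recorded day is a lower bound on
#' the continuous age at death. `interval_death_prob(params, day)` therefore
#' returns \eqn{l(day) - l(day + 1)}.
#'
#' @param params a [mortality_params()] object.
#' @param t age(s) in days, numeric `>= 0`.
#' @param day integer census day(s), `>= 1`.
#' @return `survival_prob` returns \eqn{l(t) \in (0, 1]}; `hazard_rate` the
#'   per-day hazard; `interval_death_prob` the probability of death in
#'   `[day, day + 1)`. All are vectorized over the age argument.
#' @examples
#' p <- mortality_params("logistic", a = 0.05, b = 0.2, c = 0.5)
#' survival_prob(p, 0:10)
#' hazard_rate(p, 0)         # equals a
#' interval_death_prob(p, 5) # l(5) - l(6)
#' @export
survival_prob <- function(params, t) {
  stopifnot(inherits(params, "mortality_params"))
  if (any(t < 0)) stop("age 't' must be >= 0")
  exp(log_survival(params, t))
}

#' @rdname survival_prob
#' @export
hazard_rate <- function(params, t) {
  stopifnot(inherits(params, "mortality_params"))
  if (any(t < 0)) stop("age 't' must be >= 0")
  a <- params$a; b <- params$b; cc <- params$c
  switch(params$family,
    exponential = rep_len(a, length(t)),
    gompertz    = a * exp(b * t),
    weibull     = a * b * (a * t)^(b - 1),
    logistic    = a * exp(b * t) / (1 + (a * cc / b) * expm1(b * t)))
}

#' @rdname survival_prob
#' @export
interval_death_prob <- function(params, day) {
  stopifnot(inherits(params, "mortality_params"))
  if (any(day < 1)) stop("'day' must be >= 1 (first census interval is [1, 2))")
  ls1 <- log_survival(params, day)
  ls2 <- log_survival(params, day + 1)
  # l(day) - l(day+1) = exp(ls1) * (1 - exp(ls2 - ls1)), stable deep in the
  # tail (both factors are representable; no 0 * Inf)
  out <- ifelse(is.infinite(ls1), 0, -exp(ls1) * expm1(ls2 - ls1))
  pmax(out, 0)
}
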