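# S3 methods for fitted mortality models.

#' @export
print.mortality_fit <- function(x, ...) {
  cat(sprintf("%s mortality model (%s likelihood), n = %d\n",
              x$family, x$mode, x$n))
  print(signif(coef(x), 6))
  cat(sprintf("log-likelihood %.4f, k = %d, AICc = %.4f%s\n",
              x$loglik, x$k, x$aicc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.mortality_fit <- function(object, ...) {
  out <- list(fit = object,
              mean_lifespan = mean(object$lifespans),
              range = range(object$lifespans))
  class(out) <- "summary.mortality_fit"
  out
}

#' @export
print.summary.mortality_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("observed lifespans: mean %.2f d, range [%d, %d] d\n",
              x$mean_lifespan, x$range[1], x$range[2]))
  cat(sprintf("starts tried: %d\n", x$fit$n_starts_tried))
  invisible(x)
}

#' @export
coef.mortality_fit <- function(object, ...) {
  p <- object$params
  unlist(p[c("a", "b", "c")])[seq_len(p$k)]
}

#' @export
logLik.mortality_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Predict survival, hazard or daily death probability from a fitted model
#'
#' @param object a `mortality_fit`.
#' @param t ages (days) at which to evaluate; defaults to `0:max(lifespan)`.
#' @param type `"survival"`, `"hazard"` or `"interval"` (daily death
#'   probability; requires `t >= 1`).
#' @param ... unused.
#' @return numeric vector of the requested quantity at each `t`.
#' @export
predict.mortality_fit <- function(object, t = NULL,
                                  type = c("survival", "hazard", "interval"),
                                  ...) {
  type <- match.arg(type)
  if (is.null(t)) t <- 0:max(object$lifespans)
  switch(type,
         survival = survival_prob(object$params, t),
         hazard = hazard_rate(object$params, t),
         interval = interval_death_prob(object$params, t))
}

#' Simulate integer lifespans from a fitted mortality model
#'
#' Draws daily-censored lifespans from the fitted survival curve by
#' inverse-CDF sampling (see [sample_lifespans()]).
#'
#' @param object a `mortality_fit`.
#' @param nsim number of lifespans to draw (default: the fitted `n`).
#' @param seed optional integer seed.
#' @param ... unused.
#' @return integer vector of simulated lifespans (days).
#' @export
simulate.mortality_fit <- function(object, nsim = object$n, seed = NULL, ...) {
  sample_lifespans(nsim, object$params, seed = seed)
}

#' Plot a fitted survival curve over the empirical cohort survivorship
#'
#' Draws the empirical proportion surviving at each day (step estimate from
#' the observed lifespans) and the fitted survival curve, on a logarithmic
#' survival axis as is conventional for mortality-trajectory plots.
#'
#' @param x a `mortality_fit`.
#' @param log use a logarithmic survival axis (default `TRUE`).
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, a data frame of ages and fitted survival.
#' @export
plot.mortality_fit <- function(x, log = TRUE, ...) {
  L <- x$lifespans
  tmax <- max(L) + 1
  tg <- seq(0, tmax, by = 0.25)
  fitted <- survival_prob(x$params, tg)
  emp_t <- 0:tmax
  emp_s <- vapply(emp_t, function(d) mean(L >= d), numeric(1))
  graphics::plot(tg, fitted, type = "l", col = "firebrick", lwd = 2,
                 log = if (log) "y" else "",
                 xlab = "age (days)", ylab = "proportion surviving",
                 ylim = c(max(min(emp_s[emp_s > 0]) / 2, 1e-4), 1), ...)
  keep <- emp_s > 0
  graphics::points(emp_t[keep], emp_s[keep], pch = 1, col = "grey30")
  invisible(data.frame(age = tg, survival = fitted))
}
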