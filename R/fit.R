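#' Negative log-likelihood of a mortality model for integer lifespans
#'
#' Two likelihood modes are provided. `"interval"` (the default, matching a
#' daily census in which each recorded lifespan L brackets the continuous
#' death time in \eqn{[L, L+1)}) uses the interval probability
#' \eqn{l(L) - l(L+1)}. `"density"` treats the recorded day as an exact
#' continuous death time and uses \eqn{f(L) = h(L)\,l(L)}.
#'
#' Interval probabilities that underflow to zero are clamped at `1e-300`
#' with a warning, so the objective stays finite for extreme parameters.
#'
#' @param params a [mortality_params()] object.
#' @param lifespans integer lifespans in days, all `>= 1`.
#' @param mode `"interval"` or `"density"`.
#' @return the negative log-likelihood (a single number).
#' @examples
#' p <- mortality_params("exponential", a = log(2))
#' mortality_nll(p, 1) # -log(l(1) - l(2)) = -log(0.25)
#' @export
mortality_nll <- function(params, lifespans, mode = c("interval", "density")) {
  mode <- match.arg(mode)
  lifespans <- check_lifespans(lifespans)
  tab <- tabulate_lifespans(lifespans)
  nll_from_tab(params, tab, mode)
}

# Aggregate tied integer lifespans once; likelihood evaluations then scale
# with the number of distinct days, not individuals.
tabulate_lifespans <- function(lifespans) {
  tb <- table(lifespans)
  list(days = as.integer(names(tb)), counts = as.numeric(tb),
       n = length(lifespans))
}

nll_from_tab <- function(params, tab, mode, warn_clamp = TRUE) {
  if (mode == "interval") {
    ls1 <- log_survival(params, tab$days)
    ls2 <- log_survival(params, tab$days + 1)
    p <- ifelse(is.infinite(ls1), 0, -exp(ls1) * expm1(ls2 - ls1))
    if (any(p < 1e-300)) {
      if (warn_clamp)
        warning("interval death probability underflowed; clamped at 1e-300")
      p <- pmax(p, 1e-300)
    }
    -sum(tab$counts * log(p))
  } else {
    h <- hazard_rate(params, tab$days)
    ll <- log(pmax(h, 1e-300)) + log_survival(params, tab$days)
    -sum(tab$counts * ll)
  }
}

# Build mortality_params from a log-scale parameter vector.
params_from_log <- function(family, logpar) {
  v <- exp(logpar)
  k <- model_n_params(family)
  mortality_params(family, a = v[1L],
                   b = if (k >= 2L) v[2L],
                   c = if (k == 3L) v[3L])
}

# Unvalidated fast constructor for optimizer inner loops: exp() of a finite
# log-parameter is already positive, so only finiteness needs checking.
params_from_log_fast <- function(family, logpar, k) {
  v <- exp(logpar)
  if (any(!is.finite(v)) || any(v == 0)) return(NULL)
  structure(list(family = family, a = v[1L],
                 b = if (k >= 2L) v[2L],
                 c = if (k == 3L) v[3L], k = k),
            class = "mortality_params")
}

#' Small-sample-corrected Akaike information criterion
#'
#' \eqn{AICc = -2 \ln L + 2k + 2k(k+1)/(n - k - 1)}. The sample size `n` is
#' the number of individuals (one lifespan datum per individual).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of individuals; must exceed `k + 1`.
#' @return the AICc value.
#' @examples
#' aicc(0, k = 1, n = 10) # 2 + 0.5
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.numeric(loglik), is.numeric(k), is.numeric(n))
  if (n <= k + 1) stop("AICc requires n > k + 1 (correction denominator positive)")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' Normalized relative likelihoods \eqn{w_i = \exp(-\Delta_i/2) / \sum_j
#' \exp(-\Delta_j/2)} with \eqn{\Delta_i = AICc_i - \min AICc}, interpreted
#' as the relative support for each candidate model.
#'
#' @param aicc_values numeric vector of AICc (or, equivalently, delta-AICc)
#'   values for a candidate set.
#' @return weights summing to 1, in the order of the input.
#' @examples
#' akaike_weights(c(0, 2.02, 2.17, 2.74, 3.82, 5.48, 69.73, 77.95))
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0L) stop("empty candidate set")
  if (anyNA(aicc_values) || any(!is.finite(aicc_values)))
    stop("AICc values must be finite")
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

# Default multi-start grid on the log scale (interior points of a log-spaced
# grid over a in [1e-4, 0.5], b in [1e-3, 1], c in [1e-2, 1e2]).
start_grid <- function(family) {
  ga <- log(log_grid(1e-4, 0.5, 2))
  gb <- log(log_grid(1e-3, 1, 2))
  gc <- log(log_grid(1e-2, 1e2, 2))
  switch(family,
    exponential = matrix(log(log_grid(1e-4, 0.5, 8)), ncol = 1L),
    gompertz    = ,
    weibull     = as.matrix(expand.grid(a = log(log_grid(1e-4, 0.5, 3)),
                                        b = log(log_grid(1e-3, 1, 3)))),
    logistic    = as.matrix(expand.grid(a = ga, b = gb, c = gc)))
}

# Moment-flavoured heuristic start from the mean lifespan.
heuristic_start <- function(family, lifespans) {
  m <- mean(lifespans)
  ahat <- log((1 + m) / m)   # interval-censored exponential MLE
  switch(family,
    exponential = log(ahat),
    gompertz    = log(c(ahat / 2, 0.1)),
    weibull     = log(c(1 / m, 2)),
    logistic    = log(c(ahat / 10, 0.2, 1)))
}

#' Fit a mortality model to one group's lifespans by maximum likelihood
#'
#' Maximizes the (interval-censored or density) log-likelihood of one of the
#' four mortality families over the positive parameter space, optimizing on
#' the log scale with a derivative-free simplex search restarted from a
#' log-spaced grid plus a moment-based heuristic start. For nested families
#' (Gompertz inside logistic, exponential inside Gompertz) an extra warm
#' start at the boundary of the larger family guarantees that the fitted
#' log-likelihood respects the nesting hierarchy up to optimizer tolerance.
#'
#' @param lifespans integer lifespans in days, all `>= 1`.
#' @param family model family; see [mortality_params()].
#' @param mode likelihood mode; see [mortality_nll()].
#' @param n_starts minimum number of restarts (the default grid already
#'   provides at least 8).
#' @param start optional extra starting value: a numeric vector of natural-
#'   scale parameters `(a[, b[, c]])`.
#' @param multistart set to `FALSE` (with `start` supplied) to polish from
#'   the given start only — used for warm-started bootstrap refits.
#' @return an object of class `mortality_fit` with elements `params`
#'   ([mortality_params()]), `loglik`, `k`, `n`, `aicc`, `converged`,
#'   `n_starts_tried`, `family`, `mode` and the data.
#' @examples
#' set.seed(1)
#' L <- sample_lifespans(200, mortality_params("gompertz", a = 0.01, b = 0.15))
#' fit_mortality(L, "gompertz")
#' @export
fit_mortality <- function(lifespans,
                          family = c("logistic", "gompertz", "weibull",
                                     "exponential"),
                          mode = c("interval", "density"),
                          n_starts = 8L, start = NULL, multistart = TRUE) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  lifespans <- check_lifespans(lifespans)
  k <- model_n_params(family)
  n <- length(lifespans)
  if (n < k + 2L)
    stop(sprintf("need at least %d individuals to fit the %s family (n = %d)",
                 k + 2L, family, n))
  tab <- tabulate_lifespans(lifespans)
  fn <- function(logpar) {
    p <- params_from_log_fast(family, logpar, k)
    if (is.null(p)) return(1e10)
    v <- nll_from_tab(p, tab, mode, warn_clamp = FALSE)
    if (!is.finite(v)) 1e10 else v
  }

  if (!is.null(start) && (length(start) != k || any(start <= 0)))
    stop(sprintf("'start' must be %d positive values for the %s family", k, family))
  if (!multistart && !is.null(start)) {
    starts <- matrix(log(start), nrow = 1L)
  } else {
    starts <- rbind(start_grid(family), heuristic_start(family, lifespans))
    if (!is.null(start)) starts <- rbind(starts, log(start))
    # warm starts on the nested boundary: logistic from the Gompertz optimum
    # (c ~ 0), Gompertz from the exponential optimum (b ~ 0)
    if (family == "logistic") {
      gf <- fit_mortality(lifespans, "gompertz", mode = mode)
      starts <- rbind(starts, c(log(gf$params$a), log(gf$params$b), log(1e-8)))
    } else if (family == "gompertz") {
      ef <- fit_mortality(lifespans, "exponential", mode = mode)
      starts <- rbind(starts, c(log(ef$params$a), log(1e-8)))
    }
    while (nrow(starts) < n_starts) starts <- rbind(starts, starts[1L, ] * 0.9)
  }

  best <- optimise_multistart(fn, starts, one_dim = (k == 1L))
  if (!best$converged)
    warning(sprintf("no start converged when fitting the %s family", family))

  params <- params_from_log(family, best$par)
  loglik <- -best$value
  structure(list(params = params, family = family, mode = mode,
                 loglik = loglik, k = k, n = n,
                 aicc = aicc(loglik, k, n),
                 converged = best$converged,
                 n_starts_tried = nrow(starts),
                 lifespans = lifespans,
                 call = match.call()),
            class = "mortality_fit")
}

# Run the simplex (or Brent, in one dimension) search from each start; keep
# the best converged optimum, breaking near-ties by the smaller natural-scale
# parameter norm.
optimise_multistart <- function(fn, starts, one_dim = FALSE,
                                reltol = 1e-8, maxit = 2000L) {
  results <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    par0 <- starts[i, ]
    results[[i]] <- if (one_dim) {
      tryCatch(stats::optim(par0, fn, method = "Brent",
                            lower = log(1e-8), upper = log(10),
                            control = list(maxit = maxit)),
               error = function(e) NULL)
    } else {
      tryCatch(stats::optim(par0, fn, method = "Nelder-Mead",
                            control = list(reltol = reltol, maxit = maxit)),
               error = function(e) NULL)
    }
  }
  ok <- !vapply(results, is.null, logical(1))
  results <- results[ok]
  conv <- vapply(results, function(r) r$convergence == 0L && is.finite(r$value),
                 logical(1))
  pool <- if (any(conv)) results[conv] else results
  vals <- vapply(pool, `[[`, numeric(1), "value")
  vbest <- min(vals)
  tied <- which(vals <= vbest + 1e-8)
  norms <- vapply(pool[tied], function(r) sqrt(sum(exp(r$par)^2)), numeric(1))
  chosen <- pool[[tied[which.min(norms)]]]
  list(par = chosen$par, value = chosen$value, converged = any(conv))
}

#' AICc model-selection table across mortality families
#'
#' `selection_table()` assembles fitted models (on the same data) into a
#' table sorted by delta-AICc with Akaike weights; `select_models()` is a
#' convenience wrapper that fits a set of families to one lifespan vector
#' and tabulates them.
#'
#' @param fits a list of [fit_mortality()] results on the same data.
#' @param lifespans integer lifespans in days.
#' @param families character vector of families to fit.
#' @param mode likelihood mode.
#' @param ... passed on to [fit_mortality()].
#' @return a `model_selection` data frame with columns `model`, `k`, `AICc`,
#'   `delta_AICc`, `weight`, `converged`, sorted by `delta_AICc`; the fitted
#'   objects are attached as attribute `"fits"` (named by model).
#' @examples
#' set.seed(1)
#' L <- sample_lifespans(300, mortality_params("logistic", 0.001, 0.25, 1))
#' select_models(L)
#' @export
selection_table <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1),
                                           "mortality_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("all fits in a selection table must be on the same data (equal n)")
  tb <- data.frame(
    model = vapply(fits, `[[`, character(1), "family"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AICc = vapply(fits, `[[`, numeric(1), "aicc"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  tb$delta_AICc <- tb$AICc - min(tb$AICc)
  tb$weight <- akaike_weights(tb$AICc)
  tb <- tb[order(tb$delta_AICc), c("model", "k", "AICc", "delta_AICc",
                                   "weight", "converged")]
  rownames(tb) <- NULL
  names(fits) <- vapply(fits, `[[`, character(1), "family")
  structure(tb, class = c("model_selection", "data.frame"), fits = fits)
}

#' @rdname selection_table
#' @export
select_models <- function(lifespans,
                          families = c("exponential", "gompertz", "weibull",
                                       "logistic"),
                          mode = c("interval", "density"), ...) {
  mode <- match.arg(mode)
  fits <- lapply(families, function(f)
    fit_mortality(lifespans, family = f, mode = mode, ...))
  selection_table(fits)
}

#' @export
print.model_selection <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  df$weight <- signif(df$weight, 3)
  df$AICc <- round(df$AICc, 2)
  df$delta_AICc <- round(df$delta_AICc, 2)
  cat("Model selection by AICc (best model first):\n")
  print.data.frame(df, row.names = FALSE, digits = digits)
  if (!all(df$converged))
    cat("note: one or more candidate fits did not converge\n")
  invisible(x)
}
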