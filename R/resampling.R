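#' Randomization test for a difference in group means
#'
#' Pools the two groups' values and repeatedly reassigns group labels
#' (preserving group sizes), comparing the absolute difference in group
#' means against its permutation distribution. The test is two-sided by
#' construction. Sampled permutations use the add-one correction
#' \eqn{p = (\#\{|d^*| \ge |d_{obs}|\} + 1)/(B + 1)}, so p is never
#' reported as exactly zero; exhaustive enumeration (all
#' \eqn{\binom{n_1+n_2}{n_1}} label assignments) reports the exact
#' proportion.
#'
#' @param values_g1,values_g2 numeric trait values for the two groups
#'   (each of length >= 2).
#' @param n_permutations number of sampled permutations (ignored when
#'   exhaustive).
#' @param seed optional integer seed (sampled mode).
#' @param exhaustive `TRUE`, `FALSE`, or `"auto"` (exhaustive when the
#'   number of label assignments is at most `max_exhaustive`).
#' @param max_exhaustive enumeration budget for `"auto"`.
#' @return an object of class `permutation_test`: `observed_diff`
#'   (group 1 mean - group 2 mean), `p_value`, `n_permutations`,
#'   `exhaustive`, `seed`.
#' @examples
#' permutation_test(c(1, 2, 3), c(10, 11, 12), exhaustive = TRUE) # p = 0.1
#' @export
permutation_test <- function(values_g1, values_g2, n_permutations = 10000L,
                             seed = NULL, exhaustive = "auto",
                             max_exhaustive = 20000L) {
  stopifnot(is.numeric(values_g1), is.numeric(values_g2),
            length(values_g1) >= 2L, length(values_g2) >= 2L)
  n1 <- length(values_g1); n2 <- length(values_g2)
  pooled <- c(values_g1, values_g2)
  obs <- mean(values_g1) - mean(values_g2)

  if (length(unique(pooled)) == 1L) {
    warning("all pooled values are identical; permutation p-value is 1")
    return(structure(list(observed_diff = 0, p_value = 1,
                          n_permutations = 0L, exhaustive = TRUE,
                          seed = seed), class = "permutation_test"))
  }

  n_assign <- choose(n1 + n2, n1)
  do_exhaustive <- isTRUE(exhaustive) ||
    (identical(exhaustive, "auto") && n_assign <= max_exhaustive)
  tot <- sum(pooled); n <- n1 + n2
  if (do_exhaustive) {
    idx <- utils::combn(n, n1)
    s1 <- colSums(matrix(pooled[idx], nrow = n1))
    d <- s1 / n1 - (tot - s1) / n2
    p <- mean(abs(d) >= abs(obs) - 1e-12)
    B <- ncol(idx)
  } else {
    B <- as.integer(n_permutations)
    d <- with_seed(seed, {
      vapply(seq_len(B), function(i) {
        pick <- sample.int(n, n1)
        s1 <- sum(pooled[pick])
        s1 / n1 - (tot - s1) / n2
      }, numeric(1))
    })
    p <- (sum(abs(d) >= abs(obs) - 1e-12) + 1) / (B + 1)
  }
  structure(list(observed_diff = obs, p_value = p, n_permutations = B,
                 exhaustive = do_exhaustive, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("randomization test (%s, %d permutations)\n",
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  cat(sprintf("observed mean difference: %.6g\np-value (two-sided): %.6g\n",
              x$observed_diff, x$p_value))
  invisible(x)
}

#' Stratified bootstrap CI for a difference in group means
#'
#' Resamples each group with replacement independently (the bootstrap is
#' stratified by group) and forms the percentile interval of the resampled
#' mean differences.
#'
#' @param values_g1,values_g2 numeric trait values for the two groups.
#' @param n_reps bootstrap replicates (default 10 000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return an object of class `bootstrap_ci`: `point` (observed mean
#'   difference), `lower`, `upper`, `level`, `n_reps`, `seed`.
#' @examples
#' set.seed(2)
#' bootstrap_mean_diff(rnorm(100, 10), rnorm(100, 7), n_reps = 1000)
#' @export
bootstrap_mean_diff <- function(values_g1, values_g2, n_reps = 10000L,
                                level = 0.95, seed = NULL) {
  stopifnot(length(values_g1) >= 1L, length(values_g2) >= 1L,
            level > 0, level < 1)
  if (n_reps < 100L)
    warning("fewer than 100 bootstrap replicates: percentile CI is unstable")
  n1 <- length(values_g1); n2 <- length(values_g2)
  point <- mean(values_g1) - mean(values_g2)
  d <- with_seed(seed, {
    i1 <- matrix(sample.int(n1, n1 * n_reps, replace = TRUE), nrow = n1)
    i2 <- matrix(sample.int(n2, n2 * n_reps, replace = TRUE), nrow = n2)
    colMeans(matrix(values_g1[i1], nrow = n1)) -
      colMeans(matrix(values_g2[i2], nrow = n2))
  })
  qs <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(point = point, lower = qs[1], upper = qs[2],
                 level = level, n_reps = as.integer(n_reps), seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("bootstrap %g%% CI (%d replicates): %.6g [%.6g, %.6g]\n",
              100 * x$level, x$n_reps, x$point, x$lower, x$upper))
  invisible(x)
}

#' Bootstrap CIs for fitted mortality-model parameters
#'
#' Resamples the lifespan distribution(s) with replacement within group,
#' refits the model to each replicate (warm-started from the original fit),
#' and forms percentile CIs for every parameter. For a single group supply
#' `lifespans_g1` only and a `family`; for the joint two-group analysis
#' supply both groups and a joint `spec` name such as `"Abc"`.
#'
#' @param lifespans_g1,lifespans_g2 integer lifespans; `lifespans_g2 = NULL`
#'   requests a single-group fit.
#' @param family model family for the single-group case.
#' @param spec joint candidate name for the two-group case.
#' @param n_reps bootstrap replicates.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @param mode likelihood mode.
#' @return an object of class `mortality_boot`: the original `fit`, a
#'   `draws` matrix (one row per converged replicate, one column per
#'   parameter), per-parameter percentile CIs in `ci`, and the count of
#'   non-converged replicates `n_failed` (a warning is raised above 10%).
#' @examples
#' \donttest{
#' set.seed(3)
#' L <- sample_lifespans(300, mortality_params("logistic", 0.001, 0.25, 1))
#' bootstrap_model_params(L, family = "logistic", n_reps = 100, seed = 1)
#' }
#' @export
bootstrap_model_params <- function(lifespans_g1, lifespans_g2 = NULL,
                                   family = "logistic", spec = "Abc",
                                   n_reps = 1000L, level = 0.95,
                                   seed = NULL,
                                   mode = c("interval", "density")) {
  mode <- match.arg(mode)
  joint <- !is.null(lifespans_g2)
  if (joint) {
    fit0 <- fit_mortality_joint(lifespans_g1, lifespans_g2, spec, mode = mode)
    par0 <- c(coef_params(fit0$params_g1), coef_params(fit0$params_g2))
    nm <- c(paste0(c("a", "b", "c"), "_g1"), paste0(c("a", "b", "c"), "_g2"))
  } else {
    fit0 <- fit_mortality(lifespans_g1, family, mode = mode)
    par0 <- coef(fit0)
    nm <- names(par0)
  }
  if (!fit0$converged) stop("original fit did not converge; cannot bootstrap")

  # replicate refits are polished from the original MLE (single warm start):
  # the resampled likelihood surface is a small perturbation of the original
  start0 <- if (joint) list(p1 = coef_params(fit0$params_g1),
                            p2 = coef_params(fit0$params_g2))
            else coef(fit0)
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_reps, ncol = length(par0))
    for (i in seq_len(n_reps)) {
      b1 <- sample(lifespans_g1, replace = TRUE)
      f <- if (joint) {
        b2 <- sample(lifespans_g2, replace = TRUE)
        tryCatch(suppressWarnings(
          fit_mortality_joint(b1, b2, spec, mode = mode, start = start0,
                              multistart = FALSE)),
          error = function(e) NULL)
      } else {
        tryCatch(suppressWarnings(
          fit_mortality(b1, family, mode = mode, start = start0,
                        multistart = FALSE)),
          error = function(e) NULL)
      }
      if (!is.null(f) && f$converged)
        out[i, ] <- if (joint) c(coef_params(f$params_g1),
                                 coef_params(f$params_g2))
                    else coef(f)
    }
    out
  })
  colnames(draws) <- nm
  failed <- rowSums(is.na(draws)) > 0
  n_failed <- sum(failed)
  if (n_failed > 0.1 * n_reps)
    warning(sprintf("%d of %d bootstrap replicates failed to converge (> 10%%)",
                    n_failed, n_reps))
  draws_ok <- draws[!failed, , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- t(apply(draws_ok, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(fit = fit0, draws = draws_ok,
                 ci = data.frame(parameter = nm, estimate = unname(par0),
                                 lower = ci[, 1], upper = ci[, 2],
                                 stringsAsFactors = FALSE, row.names = NULL),
                 level = level, n_reps = as.integer(n_reps),
                 n_failed = n_failed, seed = seed, joint = joint),
            class = "mortality_boot")
}

#' @export
print.mortality_boot <- function(x, ...) {
  cat(sprintf("bootstrap of %s fit: %d replicates (%d failed), %g%% percentile CIs\n",
              if (x$joint) paste0("joint '", x$fit$spec$name, "'")
              else x$fit$family,
              x$n_reps, x$n_failed, 100 * x$level))
  df <- x$ci
  df[, -1] <- signif(df[, -1], 5)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Pointwise bootstrap confidence band for a fitted survival curve
#'
#' Evaluates the logistic survival curve at each bootstrap parameter draw
#' and forms the pointwise percentile envelope on an age grid. Bands are
#' pointwise, not simultaneous.
#'
#' @param boot a [bootstrap_model_params()] result, or a numeric matrix of
#'   parameter draws with columns `(a, b, c)` (logistic) or the columns of a
#'   single-group family fit.
#' @param ages numeric age grid (days).
#' @param level band level (default 0.95).
#' @param group for a joint bootstrap, which group's curve (`1` or `2`).
#' @param family model family when `boot` is a bare matrix.
#' @return a data frame `age`, `lower`, `upper` (and `point` when the
#'   original fit is available), with attributes `level` and `pointwise`.
#' @export
survival_band <- function(boot, ages, level = 0.95, group = 1L,
                          family = "logistic") {
  if (inherits(boot, "mortality_boot")) {
    draws <- boot$draws
    if (boot$joint) {
      cols <- if (group == 1L) grep("_g1$", colnames(draws))
              else grep("_g2$", colnames(draws))
      draws <- draws[, cols, drop = FALSE]
      fam <- "logistic"
      point_params <- if (group == 1L) boot$fit$params_g1 else boot$fit$params_g2
    } else {
      fam <- boot$fit$family
      point_params <- boot$fit$params
    }
  } else {
    draws <- as.matrix(boot)
    fam <- family
    point_params <- NULL
  }
  if (nrow(draws) < 100L)
    stop("survival_band requires at least 100 parameter resamples")
  k <- model_n_params(fam)
  curves <- apply(draws, 1, function(p)
    survival_prob(mortality_params(fam, a = p[1],
                                   b = if (k >= 2) p[2],
                                   c = if (k == 3) p[3]), ages))
  curves <- matrix(curves, nrow = length(ages))
  alpha <- (1 - level) / 2
  qs <- apply(curves, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  out <- data.frame(age = ages, lower = qs[1, ], upper = qs[2, ])
  if (!is.null(point_params))
    out$point <- survival_prob(point_params, ages)
  attr(out, "level") <- level
  attr(out, "pointwise") <- TRUE
  out
}
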