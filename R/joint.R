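#' The eight candidate joint two-group logistic models
#'
#' In the joint analysis each logistic parameter (`a`, `b`, `c`) is either
#' common to the two groups or distinct between them, giving \eqn{2^3 = 8}
#' candidates. Names follow the convention that a capital letter marks a
#' distinct parameter and a lower-case letter a common one: `"Abc"` has
#' distinct initial mortality `a` but common `b` and `c`. The free-parameter
#' count is `k = 3 +` (number of distinct parameters).
#'
#' @return `joint_model_specs()` returns a data frame of all eight specs
#'   (columns `name`, `distinct_a`, `distinct_b`, `distinct_c`, `k`) in the
#'   canonical order `abc, Abc, aBc, abC, ABc, AbC, aBC, ABC`.
#'   `joint_model_spec(name)` returns the single named spec as a list.
#' @examples
#' joint_model_specs()
#' joint_model_spec("Abc")$k # 4
#' @export
joint_model_specs <- function() {
  names <- c("abc", "Abc", "aBc", "abC", "ABc", "AbC", "aBC", "ABC")
  flags <- t(vapply(names, function(nm) {
    ch <- strsplit(nm, "")[[1]]
    ch == toupper(ch)
  }, logical(3)))
  data.frame(name = names,
             distinct_a = flags[, 1], distinct_b = flags[, 2],
             distinct_c = flags[, 3],
             k = 3L + rowSums(flags),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname joint_model_specs
#' @param name a model name such as `"Abc"`; case of each of the three
#'   letters encodes distinct (upper) vs common (lower).
#' @export
joint_model_spec <- function(name) {
  specs <- joint_model_specs()
  i <- match(name, specs$name)
  if (is.na(i))
    stop("unknown joint model name '", name,
         "'; valid names: ", paste(specs$name, collapse = ", "))
  as.list(specs[i, ])
}

# Pack/unpack the reduced log-scale parameter vector for a joint spec:
# common parameters occupy a single coordinate shared by both groups.
joint_unpack <- function(theta, spec) {
  distinct <- c(spec$distinct_a, spec$distinct_b, spec$distinct_c)
  p1 <- numeric(3); p2 <- numeric(3)
  j <- 0L
  for (i in 1:3) {
    if (distinct[i]) {
      p1[i] <- theta[j + 1L]; p2[i] <- theta[j + 2L]; j <- j + 2L
    } else {
      p1[i] <- theta[j + 1L]; p2[i] <- theta[j + 1L]; j <- j + 1L
    }
  }
  list(p1 = p1, p2 = p2)
}

joint_pack <- function(logp1, logp2, spec) {
  distinct <- c(spec$distinct_a, spec$distinct_b, spec$distinct_c)
  theta <- numeric(0)
  for (i in 1:3) {
    theta <- if (distinct[i]) c(theta, logp1[i], logp2[i])
             else c(theta, (logp1[i] + logp2[i]) / 2)
  }
  theta
}

#' Fit a joint two-group logistic mortality model
#'
#' Maximizes the summed two-group log-likelihood directly in the reduced
#' parameter space of the candidate: common parameters are single
#' coordinates shared by both groups, so a common parameter is exactly equal
#' between the fitted group parameter sets. The search is warm-started from
#' the two separate single-group logistic fits and from a pooled fit, plus a
#' log-spaced grid, which stabilizes the six-parameter all-distinct
#' candidate.
#'
#' @param lifespans_g1,lifespans_g2 integer lifespans (days) of the two
#'   groups; group 1 is conventionally the first-offspring (reference)
#'   group.
#' @param spec a model name such as `"Abc"` or a spec from
#'   [joint_model_spec()].
#' @param mode likelihood mode; see [mortality_nll()].
#' @param groups length-2 character vector of group labels.
#' @param warm optional list with elements `f1`, `f2`, `pool` (single-group
#'   logistic `mortality_fit`s) to reuse across candidates.
#' @param start optional warm start: a list with natural-scale logistic
#'   parameter vectors `p1`, `p2` (length 3 each).
#' @param multistart set to `FALSE` (with `start` supplied) to polish from
#'   the given start only — used for warm-started bootstrap refits.
#' @return an object of class `joint_mortality_fit` with the spec, the two
#'   groups' [mortality_params()] (common components identical), `loglik`,
#'   `k`, `n = n1 + n2`, `aicc`, and convergence information.
#' @examples
#' set.seed(1)
#' g1 <- sample_lifespans(150, mortality_params("logistic", 1e-4, 0.3, 1))
#' g2 <- sample_lifespans(150, mortality_params("logistic", 1e-3, 0.3, 1))
#' fit_mortality_joint(g1, g2, "Abc")
#' @export
fit_mortality_joint <- function(lifespans_g1, lifespans_g2, spec = "ABC",
                                mode = c("interval", "density"),
                                groups = c("group1", "group2"),
                                warm = NULL, start = NULL,
                                multistart = TRUE) {
  mode <- match.arg(mode)
  if (is.character(spec)) spec <- joint_model_spec(spec)
  lifespans_g1 <- check_lifespans(lifespans_g1, "lifespans_g1")
  lifespans_g2 <- check_lifespans(lifespans_g2, "lifespans_g2")
  n <- length(lifespans_g1) + length(lifespans_g2)
  k <- spec$k
  if (n <= k + 1L) stop("too few individuals for a joint fit (need n > k + 1)")

  tab1 <- tabulate_lifespans(lifespans_g1)
  tab2 <- tabulate_lifespans(lifespans_g2)
  fn <- function(theta) {
    up <- joint_unpack(theta, spec)
    p1 <- params_from_log_fast("logistic", up$p1, 3L)
    p2 <- params_from_log_fast("logistic", up$p2, 3L)
    if (is.null(p1) || is.null(p2)) return(1e10)
    v <- nll_from_tab(p1, tab1, mode, warn_clamp = FALSE) +
         nll_from_tab(p2, tab2, mode, warn_clamp = FALSE)
    if (!is.finite(v)) 1e10 else v
  }

  if (!multistart && !is.null(start)) {
    starts <- matrix(joint_pack(log(start$p1), log(start$p2), spec), nrow = 1L)
  } else {
    if (is.null(warm)) warm <- joint_warm_fits(lifespans_g1, lifespans_g2, mode)
    l1 <- log(coef(warm$f1)); l2 <- log(coef(warm$f2)); lp <- log(coef(warm$pool))
    starts <- rbind(joint_pack(l1, l2, spec),
                    joint_pack(lp, lp, spec))
    if (!is.null(start))
      starts <- rbind(starts, joint_pack(log(start$p1), log(start$p2), spec))
    grid <- start_grid("logistic")
    for (i in seq_len(nrow(grid)))
      starts <- rbind(starts, joint_pack(grid[i, ], grid[i, ], spec))
  }

  best <- optimise_multistart(fn, starts)
  if (!best$converged)
    warning(sprintf("no start converged for joint model '%s'", spec$name))
  up <- joint_unpack(best$par, spec)
  loglik <- -best$value
  structure(list(spec = spec,
                 params_g1 = params_from_log("logistic", up$p1),
                 params_g2 = params_from_log("logistic", up$p2),
                 groups = groups, mode = mode,
                 loglik = loglik, k = k, n = n,
                 n_g1 = length(lifespans_g1), n_g2 = length(lifespans_g2),
                 aicc = aicc(loglik, k, n),
                 converged = best$converged,
                 n_starts_tried = nrow(starts),
                 lifespans_g1 = lifespans_g1, lifespans_g2 = lifespans_g2),
            class = "joint_mortality_fit")
}

joint_warm_fits <- function(lifespans_g1, lifespans_g2, mode) {
  list(f1 = fit_mortality(lifespans_g1, "logistic", mode = mode),
       f2 = fit_mortality(lifespans_g2, "logistic", mode = mode),
       pool = fit_mortality(c(lifespans_g1, lifespans_g2), "logistic",
                            mode = mode))
}

#' @export
print.joint_mortality_fit <- function(x, ...) {
  cat(sprintf("joint two-group logistic model '%s' (k = %d, n = %d + %d)\n",
              x$spec$name, x$k, x$n_g1, x$n_g2))
  m <- rbind(coef_params(x$params_g1), coef_params(x$params_g2))
  rownames(m) <- x$groups
  print(signif(m, 6))
  cat(sprintf("log-likelihood %.4f, AICc = %.4f%s\n", x$loglik, x$aicc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

coef_params <- function(p) unlist(p[c("a", "b", "c")])[seq_len(p$k)]

#' @export
coef.joint_mortality_fit <- function(object, ...) {
  m <- rbind(coef_params(object$params_g1), coef_params(object$params_g2))
  rownames(m) <- object$groups
  m
}

#' @export
logLik.joint_mortality_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' AICc selection over the eight joint two-group logistic candidates
#'
#' Fits every candidate of [joint_model_specs()] to the two groups and
#' tabulates them by delta-AICc with Akaike weights. The AICc sample size is
#' the total number of individuals.
#'
#' @inheritParams fit_mortality_joint
#' @return a `model_selection` data frame with columns `model`, `a_status`,
#'   `b_status`, `c_status`, `k`, `AICc`, `delta_AICc`, `weight`,
#'   `converged`, sorted by `delta_AICc`; fitted objects attached as
#'   attribute `"fits"`.
#' @examples
#' \donttest{
#' set.seed(1)
#' g1 <- sample_lifespans(200, mortality_params("logistic", 1e-4, 0.3, 1))
#' g2 <- sample_lifespans(200, mortality_params("logistic", 1e-3, 0.3, 1))
#' joint_model_selection(g1, g2, groups = c("first", "fifth"))
#' }
#' @export
joint_model_selection <- function(lifespans_g1, lifespans_g2,
                                  mode = c("interval", "density"),
                                  groups = c("group1", "group2")) {
  mode <- match.arg(mode)
  warm <- joint_warm_fits(lifespans_g1, lifespans_g2, mode)
  specs <- joint_model_specs()
  fits <- lapply(specs$name, function(nm)
    fit_mortality_joint(lifespans_g1, lifespans_g2, nm, mode = mode,
                        groups = groups, warm = warm))
  names(fits) <- specs$name
  status <- function(d) ifelse(d, "distinct", "common")
  tb <- data.frame(
    model = specs$name,
    a_status = status(specs$distinct_a),
    b_status = status(specs$distinct_b),
    c_status = status(specs$distinct_c),
    k = specs$k,
    AICc = vapply(fits, `[[`, numeric(1), "aicc"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  tb$delta_AICc <- tb$AICc - min(tb$AICc)
  tb$weight <- akaike_weights(tb$AICc)
  tb <- tb[order(tb$delta_AICc),
           c("model", "a_status", "b_status", "c_status", "k", "AICc",
             "delta_AICc", "weight", "converged")]
  rownames(tb) <- NULL
  structure(tb, class = c("model_selection", "data.frame"), fits = fits)
}
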