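test_that("negative log-likelihood matches hand-computed interval terms", {
  # single individual dying in [1, 2) under a = log 2: -log(1/2 - 1/4)
  expect_equal(mortality_nll(expo(log(2)), 1), -log(0.25), tolerance = 1e-12)
  expect_error(mortality_nll(expo(0.1), integer(0)), "empty")
  expect_error(mortality_nll(expo(0.1), c(2, 0)), ">= 1")
})

test_that("interval-censored exponential MLE equals the closed form", {
  # all lifespans equal 4: a-hat = log(5/4), derived analytically
  fit <- fit_mortality(rep(4L, 30), "exponential")
  expect_equal(unname(coef(fit)["a"]), log(5 / 4), tolerance = 1e-6)
  # arbitrary datasets (oracle equivalence, a sample of the acceptance sweep)
  set.seed(11)
  for (i in 1:10) {
    L <- sample.int(40, size = sample(10:60, 1), replace = TRUE)
    fit <- fit_mortality(L, "exponential")
    expect_equal(unname(coef(fit)["a"]), exp_mle_closed_form(L),
                 tolerance = 1e-6)
  }
})

test_that("AICc arithmetic is exact and reduces to AIC as n grows", {
  expect_equal(aicc(0, k = 1, n = 10), 2.5)
  expect_equal(aicc(-100, k = 3, n = 191), 206.1283422459893, tolerance = 1e-12)
  expect_equal(aicc(-50, k = 2, n = 1e9), -2 * (-50) + 4, tolerance = 1e-6)
  expect_error(aicc(0, k = 3, n = 4), "n > k \\+ 1")
})

test_that("Akaike weights normalize, order inversely to delta, and match degenerate cases", {
  expect_equal(akaike_weights(100), 1)
  expect_equal(akaike_weights(rep(7, 4)), rep(0.25, 4))
  w <- akaike_weights(c(3, 1, 5))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(order(w, decreasing = TRUE) == order(c(3, 1, 5))))
})

test_that("Gompertz parameters are recovered from a large simulated cohort", {
  L <- sample_lifespans(5000, gomp(0.005, 0.15), seed = 101)
  fit <- fit_mortality(L, "gompertz")
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)["a"] - 0.005) / 0.005, 0.10)
  expect_lt(abs(coef(fit)["b"] - 0.15) / 0.15, 0.10)
})

test_that("fitted log-likelihoods respect the nesting hierarchy", {
  set.seed(21)
  datasets <- list(
    sample_lifespans(300, logi(0.001, 0.25, 1)),
    sample_lifespans(300, gomp(0.01, 0.2)),
    sample.int(30, 300, replace = TRUE))
  for (L in datasets) {
    ll <- vapply(c("exponential", "gompertz", "logistic"),
                 function(f) fit_mortality(L, f)$loglik, numeric(1))
    expect_gte(ll["gompertz"], ll["exponential"] - 1e-6)
    expect_gte(ll["logistic"], ll["gompertz"] - 1e-6)
  }
})

test_that("fitting is invariant to the order of the input lifespans", {
  L <- sample_lifespans(400, logi(0.001, 0.25, 1), seed = 31)
  f1 <- fit_mortality(L, "logistic")
  f2 <- fit_mortality(sample(L), "logistic")
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loglik, f2$loglik)
})

test_that("selection tables rank a large logistic cohort correctly and are consistent", {
  L <- sample_lifespans(2000, logi(0.001, 0.25, 1), seed = 41)
  tb <- select_models(L)
  expect_equal(tb$model[1], "logistic")
  expect_equal(sum(tb$weight), 1, tolerance = 1e-12)
  expect_equal(min(tb$delta_AICc), 0)
  expect_true(!is.unsorted(tb$delta_AICc))
  # AICc recomputes from (loglik, k, n) for every stored fit
  for (f in attr(tb, "fits"))
    expect_equal(f$aicc, aicc(f$loglik, f$k, f$n), tolerance = 1e-12)
})

test_that("selection tables refuse fits on different data", {
  f1 <- fit_mortality(sample.int(20, 50, replace = TRUE), "exponential")
  f2 <- fit_mortality(sample.int(20, 60, replace = TRUE), "exponential")
  expect_error(selection_table(list(f1, f2)), "same data")
})

test_that("density mode gives a finite, different likelihood usable for sensitivity analysis", {
  L <- sample_lifespans(200, gomp(0.01, 0.2), seed = 51)
  f_int <- fit_mortality(L, "gompertz", mode = "interval")
  f_den <- fit_mortality(L, "gompertz", mode = "density")
  expect_true(is.finite(f_den$loglik))
  expect_false(identical(f_int$loglik, f_den$loglik))
  # estimates agree loosely (daily censoring is mild at these scales)
  expect_lt(abs(coef(f_den)["b"] - coef(f_int)["b"]) / coef(f_int)["b"], 0.3)
})
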