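test_that("permutation test handles identity, exhaustive enumeration, and degenerate input", {
  x <- c(3, 5, 7, 9)
  r <- permutation_test(x, x, n_permutations = 200, seed = 1)
  expect_equal(r$observed_diff, 0)
  expect_equal(r$p_value, 1)

  # full enumeration of C(6,3) = 20 label assignments: only the observed
  # split and its mirror reach |diff| = 10, so p = 2/20
  r2 <- permutation_test(c(1, 2, 3), c(10, 11, 12), exhaustive = TRUE)
  expect_true(r2$exhaustive)
  expect_equal(r2$p_value, 0.1)

  expect_warning(r3 <- permutation_test(rep(2, 5), rep(2, 5)), "identical")
  expect_equal(r3$p_value, 1)
})

test_that("sampled permutation p agrees with exhaustive p on small inputs", {
  set.seed(7)
  for (i in 1:3) {
    x <- rnorm(5); y <- rnorm(5, mean = 1)
    pe <- permutation_test(x, y, exhaustive = TRUE)$p_value
    ps <- permutation_test(x, y, n_permutations = 1e5, seed = i,
                           exhaustive = FALSE)$p_value
    expect_lt(abs(pe - ps), 0.02)
  }
})

test_that("sampled permutation p respects the add-one floor and the seed contract", {
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40, mean = 5)
  r <- permutation_test(x, y, n_permutations = 999, seed = 5, exhaustive = FALSE)
  expect_gte(r$p_value, 1 / 1000)
  r2 <- permutation_test(x, y, n_permutations = 999, seed = 5, exhaustive = FALSE)
  expect_identical(r$p_value, r2$p_value)
})

test_that("bootstrap mean-difference CI is degenerate for constants and matches normal theory", {
  expect_warning(
    b0 <- bootstrap_mean_diff(rep(5, 4), rep(2, 6), n_reps = 50, seed = 1),
    "100")
  expect_equal(c(b0$point, b0$lower, b0$upper), c(3, 3, 3))

  set.seed(9)
  x <- rnorm(200, 10, 1); y <- rnorm(200, 7, 1)
  b <- bootstrap_mean_diff(x, y, n_reps = 4000, seed = 2)
  expect_gte(b$point, b$lower)
  expect_lte(b$point, b$upper)
  expect_true(b$lower < 3 && b$upper > 3)
  # normal-theory width 2 * 1.96 * sqrt(2/200) ~ 0.392
  expect_lt(abs((b$upper - b$lower) - 0.392) / 0.392, 0.25)
})

test_that("parameter bootstrap is seed-deterministic and covers the truth", {
  L <- sample_lifespans(1000, logi(0.001, 0.25, 1), seed = 71)
  b1 <- bootstrap_model_params(L, family = "logistic", n_reps = 2, seed = 3)
  b2 <- bootstrap_model_params(L, family = "logistic", n_reps = 2, seed = 3)
  expect_identical(b1$draws, b2$draws)

  b <- bootstrap_model_params(L, family = "logistic", n_reps = 200, seed = 4)
  ci_b <- b$ci[b$ci$parameter == "b", ]
  expect_true(ci_b$lower <= 0.25 && ci_b$upper >= 0.25)
  expect_lte(b$n_failed, 20)
})

test_that("bootstrap CIs shrink when the sample size doubles", {
  L <- sample_lifespans(400, logi(0.001, 0.25, 1), seed = 72)
  L2 <- rep(L, 2)
  b1 <- bootstrap_model_params(L, family = "logistic", n_reps = 150, seed = 5)
  b2 <- bootstrap_model_params(L2, family = "logistic", n_reps = 150, seed = 6)
  w1 <- b1$ci$upper[2] - b1$ci$lower[2]
  w2 <- b2$ci$upper[2] - b2$ci$lower[2]
  expect_lt(w2, w1)
})

test_that("survival bands are pointwise percentile envelopes with the right edge cases", {
  # identical resamples give a zero-width band equal to the curve
  draws <- matrix(rep(c(0.001, 0.25, 1), each = 150), ncol = 3)
  ages <- 0:30
  band <- survival_band(draws, ages, family = "logistic")
  expect_equal(band$lower, band$upper)
  expect_equal(band$lower, survival_prob(logi(0.001, 0.25, 1), ages))
  # band at t = 0 is [1, 1] for any draws
  expect_equal(band$lower[1], 1)
  expect_equal(band$upper[1], 1)
  expect_error(survival_band(draws[1:50, ], ages), "100")

  # band from a real bootstrap contains the point-estimate curve
  L <- sample_lifespans(600, logi(0.001, 0.25, 1), seed = 73)
  b <- bootstrap_model_params(L, family = "logistic", n_reps = 200, seed = 7)
  band2 <- survival_band(b, ages)
  expect_true(all(band2$point >= band2$lower - 1e-12))
  expect_true(all(band2$point <= band2$upper + 1e-12))
  expect_true(attr(band2, "pointwise"))
})
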