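test_that("survival is 1 at birth and matches closed-form oracle values", {
  for (p in param_pool) expect_identical(survival_prob(p, 0), 1)

  # logistic survival at (a=0.05, b=0.2, c=0.5, t=5); arbitrary-precision value
  expect_equal(survival_prob(logi(0.05, 0.2, 0.5), 5),
               0.677643060509266, tolerance = 1e-12)
  # exponential and Gompertz closed forms
  expect_equal(survival_prob(expo(0.1), 7), exp(-0.7), tolerance = 1e-14)
  expect_equal(survival_prob(gomp(0.01, 0.1), 10),
               0.842123852062643, tolerance = 1e-12)
})

test_that("hazard matches its defining forms, with h(0) = a where applicable", {
  expect_equal(hazard_rate(logi(0.02, 0.3, 1), 0), 0.02)
  expect_equal(hazard_rate(gomp(0.02, 0.3), 0), 0.02)
  expect_equal(hazard_rate(expo(0.1), 37), 0.1)
  expect_equal(hazard_rate(gomp(0.01, 0.2), 5),
               0.0271828182845905, tolerance = 1e-12)
})

test_that("survival is non-increasing in age for every family", {
  tg <- seq(0, 80, by = 0.5)
  for (p in param_pool) {
    s <- survival_prob(p, tg)
    expect_true(all(diff(s) <= 0), info = p$family)
    expect_true(all(s >= 0 & s <= 1), info = p$family)
    # strictly positive wherever the log-survival is representable
    ls <- lansing:::log_survival(p, tg)
    expect_true(all(s[ls > -700] > 0), info = p$family)
  }
})

test_that("survival equals exp(-integrated hazard) within quadrature tolerance", {
  for (p in param_pool) {
    for (t1 in c(2, 7, 15)) {
      # Weibull with shape < 1 has an integrable singularity at 0; start
      # the quadrature at machine-small epsilon
      q <- integrate(function(u) hazard_rate(p, u), 1e-12, t1,
                     rel.tol = 1e-10)$value
      expect_equal(survival_prob(p, t1), exp(-q), tolerance = 1e-8,
                   info = p$family)
    }
  }
})

test_that("nesting limits: logistic -> Gompertz (c -> 0), Gompertz -> exponential (b -> 0)", {
  tg <- seq(0, 50, by = 0.1)
  d1 <- max(abs(survival_prob(logi(0.01, 0.1, 1e-8), tg) -
                survival_prob(gomp(0.01, 0.1), tg)))
  expect_lt(d1, 1e-6)
  d2 <- max(abs(survival_prob(gomp(0.02, 1e-8), tg) -
                survival_prob(expo(0.02), tg)))
  expect_lt(d2, 1e-6)
})

test_that("daily death probabilities telescope to the day-1 survival", {
  # geometric halving under exponential with a = log 2
  expect_equal(interval_death_prob(expo(log(2)), 1), 0.25, tolerance = 1e-14)
  # difference of two survival evaluations
  p <- logi(0.05, 0.2, 0.5)
  expect_equal(interval_death_prob(p, 5),
               survival_prob(p, 5) - survival_prob(p, 6), tolerance = 1e-14)
  expect_equal(interval_death_prob(p, 5), 0.0767312517597829,
               tolerance = 1e-12)
  # telescoping sum over a long horizon recovers l(1)
  g <- gomp(0.01, 0.2)
  expect_equal(sum(interval_death_prob(g, 1:1e4)),
               survival_prob(g, 1), tolerance = 1e-10)
  # finite-horizon identity: sum + tail = l(1) exactly up to rounding
  for (p in param_pool) {
    D <- 40L
    expect_equal(sum(interval_death_prob(p, 1:D)) + survival_prob(p, D + 1),
                 survival_prob(p, 1), tolerance = 1e-12, info = p$family)
  }
})

test_that("invalid parameters and domains are rejected", {
  expect_error(mortality_params("logistic", a = -1, b = 0.1, c = 1), "'a'")
  expect_error(mortality_params("gompertz", a = 0.1), "'b'")
  expect_error(mortality_params("logistic", a = 0.1, b = 0.1, c = 0), "'c'")
  expect_error(survival_prob(expo(0.1), -1), ">= 0")
  expect_error(interval_death_prob(expo(0.1), 0), ">= 1")
})
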