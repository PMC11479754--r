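test_that("leslie_r matches closed-form roots of the Euler-Lotka equation", {
  expect_equal(as.numeric(leslie_r(1)), 0)
  expect_equal(as.numeric(leslie_r(2)), log(2), tolerance = 1e-12)
  # fecundity (1, 1): lambda is the golden ratio
  expect_equal(as.numeric(leslie_r(c(1, 1))), 0.48121182505960347,
               tolerance = 1e-10)
  # a single offspring on day 3 is still exact replacement
  expect_equal(as.numeric(leslie_r(c(0, 0, 1))), 0, tolerance = 1e-12)
  expect_error(leslie_r(c(0, 0, 0)), "undefined")
  expect_error(leslie_r(numeric(0)))
})

test_that("Euler-Lotka root and Leslie-matrix eigenvalue agree on random schedules", {
  set.seed(12)
  for (i in 1:200) {
    m <- random_schedule()
    r <- leslie_r(m, check = FALSE)
    lam_eig <- lansing:::leslie_lambda_eigen(m)
    expect_lt(abs(attr(r, "lambda") - lam_eig), 1e-10)
  }
})

test_that("r increases with extra or earlier reproduction", {
  set.seed(13)
  for (i in 1:50) {
    m <- random_schedule()
    if (sum(m) < 2) m[length(m)] <- m[length(m)] + 2L  # ensure lambda > 1
    r0 <- as.numeric(leslie_r(m))
    # one extra offspring on a random day strictly increases r
    j <- sample.int(length(m), 1)
    m_plus <- m; m_plus[j] <- m_plus[j] + 1L
    expect_gt(as.numeric(leslie_r(m_plus)), r0)
    # moving one offspring a day earlier strictly increases r (lambda > 1)
    day <- which(m > 0 & seq_along(m) > 1)
    if (length(day) > 0) {
      d <- day[1]
      m_early <- m; m_early[d] <- m_early[d] - 1L
      m_early[d - 1] <- m_early[d - 1] + 1L
      if (m_early[length(m_early)] >= 1)
        expect_gt(as.numeric(leslie_r(m_early)), r0)
    }
  }
})

test_that("individual summaries compute AFR, totals and r, flagging zero-offspring schedules", {
  s <- summarize_individual(c(0, 1, 0, 2, 1), id = "x", group = "first")
  expect_equal(s$lifespan, 5)
  expect_equal(s$age_first_repro, 2)
  expect_equal(s$total_offspring, 4)
  expect_equal(s$r, log(attr(leslie_r(c(0, 1, 0, 2, 1)), "lambda")),
               tolerance = 1e-12)
  expect_warning(s0 <- summarize_individual(c(0, 0), id = "z"), "no offspring")
  expect_true(is.na(s0$r))
})

test_that("the schedule validator enforces the operational death definition", {
  expect_silent(lansing:::validate_schedule(c(0, 1)))
  expect_error(lansing:::validate_schedule(c(1, 0), id = "bad"),
               "death definition")
  expect_error(lansing:::validate_schedule(integer(0)))
})

test_that("cohort summaries aggregate exactly and validate group labels", {
  coh <- data.frame(
    individual_id = c("a", "b", "b"),
    group = c("first", "fifth", "fifth"),
    day = c(1L, 1L, 2L),
    offspring_count = c(1L, 0L, 2L))
  cs <- cohort_summaries(coh)
  # one individual per group, m = [1] vs m = [0, 2]
  expect_equal(unname(cs$group_means["first", "total_offspring"]), 1)
  expect_equal(unname(cs$group_means["fifth", "total_offspring"]), 2)
  d <- cs$differences
  expect_equal(d$mean_diff[d$trait == "lifespan"], 1 - 2)
  expect_equal(d$mean_diff[d$trait == "r"],
               0 - as.numeric(leslie_r(c(0, 2))), tolerance = 1e-10)
  expect_error(cohort_summaries(coh, groups = c("first", "third")),
               "outside the declared groups")

  # group means of total offspring equal sum of totals / n exactly
  coh2 <- generate_cohort(cohort_config(n = c(first = 20, fifth = 20), seed = 5))
  cs2 <- cohort_summaries(coh2)
  ind <- cs2$individuals
  for (g in c("first", "fifth"))
    expect_equal(unname(cs2$group_means[g, "total_offspring"]),
                 sum(ind$total_offspring[ind$group == g]) / sum(ind$group == g))
})
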