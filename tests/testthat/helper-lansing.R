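# Shared fixtures, generated in code.

logi <- function(a, b, c) mortality_params("logistic", a = a, b = b, c = c)
gomp <- function(a, b) mortality_params("gompertz", a = a, b = b)
weib <- function(a, b) mortality_params("weibull", a = a, b = b)
expo <- function(a) mortality_params("exponential", a = a)

# A small pool of valid parameter sets spanning all four families.
param_pool <- list(
  expo(0.05), expo(0.2),
  gomp(0.01, 0.2), gomp(0.005, 0.1),
  weib(0.05, 2), weib(0.1, 0.8),
  logi(0.001, 0.25, 1), logi(0.05, 0.2, 0.5), logi(0.01, 0.1, 5)
)

# Random fecundity schedule obeying the death definition (positive final
# day), lengths 1..max_len, counts 0..max_count.
random_schedule <- function(max_len = 30L, max_count = 3L) {
  L <- sample.int(max_len, 1L)
  m <- sample(0:max_count, L, replace = TRUE)
  m[L] <- max(1L, m[L])
  m
}

# Closed-form interval-censored exponential MLE: a-hat = log((1 + mean)/mean).
exp_mle_closed_form <- function(lifespans) log((1 + mean(lifespans)) / mean(lifespans))
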