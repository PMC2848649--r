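test_that("discrete log-density covers uniform, delta and normalization", {
  u <- cpt_params(mdarray(5, rep(0.2, 5)))
  for (k in 1:5)
    expect_equal(discrete_log_density(u, integer(), k), log(0.2))

  d <- cpt_params(cm2md(rbind(c(0, 1, 0)), integer(), 3L))
  expect_equal(discrete_log_density(d, integer(), 2), 0)
  expect_equal(discrete_log_density(d, integer(), 1), -Inf)

  set.seed(3)
  p <- cpt_params(cm2md(random_stochastic_matrix(6, 4), c(2, 3), 4))
  tot <- sum(exp(vapply(1:4, function(k)
    discrete_log_density(p, c(2, 3), k), 0)))
  expect_equal(tot, 1, tolerance = 1e-12)

  expect_error(discrete_log_density(p, c(2, 4), 1), "range")
  expect_error(discrete_log_density(p, c(2, 3), 5), "range")
})

test_that("discrete sampling is reproducible and matches its table", {
  d <- cpt_params(cm2md(rbind(c(0, 1, 0)), integer(), 3L))
  for (i in 1:10) expect_equal(discrete_sample(d, integer()), 2L)

  u <- cpt_params(mdarray(5, rep(0.2, 5)))
  set.seed(11)
  draws <- replicate(1e5, discrete_sample(u, integer()))
  freq <- tabulate(draws, 5) / 1e5
  expect_true(all(abs(freq - 0.2) < 0.01))

  set.seed(42); a <- discrete_sample(u, integer())
  set.seed(42); b <- discrete_sample(u, integer())
  expect_identical(a, b)
})

test_that("the CPT M-step reproduces the closed-form ML update", {
  p <- discrete_m_step(rbind(c(3, 1)), 0, integer(), 2L)
  expect_equal(p$prob[1, ], c(0.75, 0.25))
  p <- discrete_m_step(rbind(c(0, 0)), 0, integer(), 2L)
  expect_equal(p$prob[1, ], c(0.5, 0.5))
  p <- discrete_m_step(rbind(c(3, 1)), 1, integer(), 2L)
  expect_equal(p$prob[1, ], c(4 / 6, 2 / 6))
  expect_error(discrete_m_step(rbind(c(-1, 2)), 0, integer(), 2L), "nonnegative")
})

test_that("M-step then density reproduces empirical frequencies exactly", {
  set.seed(4)
  x <- sample.int(4, 500, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  counts <- tabulate(x, 4)
  p <- discrete_m_step(rbind(counts), 0, integer(), 4L)
  expect_equal(exp(vapply(1:4, function(k)
    discrete_log_density(p, integer(), k), 0)), counts / 500)
})

test_that("sampling then re-estimating recovers a random CPT within 0.01", {
  set.seed(7)
  prob <- random_stochastic_matrix(1, 5)
  p <- cpt_params(cm2md(prob, integer(), 5))
  draws <- replicate(1e5, discrete_sample(p, integer()))
  est <- tabulate(draws, 5) / 1e5
  expect_true(all(abs(est - prob) < 0.01))
})

test_that("Poisson node density, normalization and ML behave", {
  p <- poisson_params(1, integer())
  expect_equal(poisson_log_density(p, integer(), 0), -1)
  p2 <- poisson_params(2.5, integer())
  tot <- sum(exp(vapply(0:200, function(k)
    poisson_log_density(p2, integer(), k), 0)))
  expect_equal(tot, 1, tolerance = 1e-12)
  expect_error(poisson_log_density(p2, integer(), -1), "nonnegative")
  ## ML update is the sample mean
  st <- list(W = 2, Sk = 6)
  fit <- gibbsdbn:::family_m_step("poisson", st, p2, integer(), 1L,
                                  em_config())
  expect_equal(fit$rates, 3)
})

test_that("multinomial node log-pmf includes the coefficient and sums to 1", {
  p <- multinomial_params(rbind(c(0.5, 0.5)), integer(), 2L)
  expect_equal(multinomial_log_density(p, integer(), c(1, 1)), log(0.5))
  expect_equal(multinomial_log_density(p, integer(), c(3, 0)), 3 * log(0.5))
  ## all splits of n = 3 over 2 categories
  q <- multinomial_params(rbind(c(0.3, 0.7)), integer(), 2L)
  tot <- sum(vapply(0:3, function(k)
    exp(multinomial_log_density(q, integer(), c(k, 3 - k))), 0))
  expect_equal(tot, 1, tolerance = 1e-12)
  expect_error(multinomial_log_density(p, integer(), c(1, 1, 1)), "categories")
})
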