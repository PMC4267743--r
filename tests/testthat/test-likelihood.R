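test_that("n = 2 likelihood is the two-factor PAC product", {
  h <- toy_haplotypes(2, 6, L = 8)
  th <- estimate_theta(2)
  expect_equal(
    pac_log_likelihood(h, rho = 0.7, gamma = 0.5, lam = 0.3),
    first_haplotype_log_prob(6) +
      conditional_log_prob(h$alleles[2, ], h$alleles[1, , drop = FALSE],
                           h$positions, 0.7, 0.5, 0.3, th))
})

test_that("small-sample PAC product agrees with the enumeration oracle", {
  set.seed(31)
  h <- haplotypes(matrix(sample(0:1, 9, TRUE), 3, 3), sort(runif(3, 0, 5)), 5)
  th <- estimate_theta(3)
  want <- first_haplotype_log_prob(3) +
    oracle_conditional(h$alleles[2, ], h$alleles[1, , drop = FALSE],
                       h$positions, 1, 1.5, 0.4, th) +
    oracle_conditional(h$alleles[3, ], h$alleles[1:2, ], h$positions,
                       1, 1.5, 0.4, th)
  expect_equal(pac_log_likelihood(h, 1, 1.5, 0.4), want, tolerance = 1e-10)
})

test_that("first-haplotype factor is flat in the rates and cancels in the LRT", {
  expect_equal(first_haplotype_log_prob(1), log(0.5))
  h <- toy_haplotypes(5, 12)
  # removing the constant factor shifts the log-likelihood by exactly S log 2
  full <- pac_log_likelihood(h, 1, 0.5, 0.3)
  bare <- meiotest:::.pac_loglik_cpp(h$alleles, h$positions, 1, 0.5, 0.3,
                                     estimate_theta(5), FALSE, FALSE)
  expect_equal(full - first_haplotype_log_prob(12), bare, tolerance = 1e-10)
  # so any statistic differencing two such objectives is unchanged by it
  l0 <- pac_log_likelihood(h, 1, crossover_only = TRUE)
  expect_equal(-2 * (l0 - full),
               -2 * ((l0 - first_haplotype_log_prob(12)) - bare),
               tolerance = 1e-10)
})

test_that("tract-length prior is calibrated and proper", {
  f <- function(l) exp(log_prior_lambda(l))
  expect_equal(integrate(f, 0.05, 2)$value, 0.9545, tolerance = 1e-3)
  expect_equal(integrate(f, 0, Inf)$value, 1, tolerance = 1e-6)
  expect_equal(integrate(f, 0, 10^-0.5)$value, 0.5, tolerance = 1e-6)
  expect_identical(log_prior_lambda(-1), -Inf)
  expect_identical(log_prior_lambda(0), -Inf)
})

test_that("posterior objective = likelihood + prior, prior dropped at gamma = 0", {
  h <- toy_haplotypes(4, 10)
  expect_equal(log_posterior(h, 1, 0.8, 0.4),
               pac_log_likelihood(h, 1, 0.8, 0.4) + log_prior_lambda(0.4))
  expect_equal(log_posterior(h, 1, 0, 0),
               pac_log_likelihood(h, 1, crossover_only = TRUE))
})

test_that("likelihood is invariant to joint kb rescaling", {
  h <- toy_haplotypes(5, 14, L = 20)
  h10 <- haplotypes(h$alleles, h$positions * 10, h$region_length * 10)
  expect_equal(pac_log_likelihood(h, 1.2, 0.6, 0.5),
               pac_log_likelihood(h10, 0.12, 0.06, 5), tolerance = 1e-12)
})

test_that("order-averaged likelihood is reproducible and order-stabilised", {
  h <- toy_haplotypes(6, 10)
  a1 <- pac_log_likelihood(h, 1, 0.5, 0.4, order = "averaged",
                           n_orders = 6, order_seed = 11)
  a2 <- pac_log_likelihood(h, 1, 0.5, 0.4, order = "averaged",
                           n_orders = 6, order_seed = 11)
  expect_identical(a1, a2)
  # the averaged value has the same expectation for a row-permuted matrix:
  # over many order seeds the two means coincide within Monte-Carlo error
  hp <- haplotypes(h$alleles[c(3, 1, 6, 2, 5, 4), ], h$positions,
                   h$region_length)
  v1 <- vapply(1:40, function(s)
    pac_log_likelihood(h, 1, 0.5, 0.4, order = "averaged", n_orders = 2,
                       order_seed = s), 1.0)
  v2 <- vapply(1:40, function(s)
    pac_log_likelihood(hp, 1, 0.5, 0.4, order = "averaged", n_orders = 2,
                       order_seed = s), 1.0)
  se <- sqrt(var(v1) / 40 + var(v2) / 40)
  expect_lt(abs(mean(v1) - mean(v2)), 4 * se + 1e-9)
  # fixed-order value does depend on row order (the reason averaging exists)
  expect_false(isTRUE(all.equal(pac_log_likelihood(h, 1, 0.5, 0.4),
                                pac_log_likelihood(hp, 1, 0.5, 0.4))))
})
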