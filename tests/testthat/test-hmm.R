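test_that("per-site mutation parameter follows the harmonic form", {
  expect_equal(estimate_theta(2), 1)
  expect_equal(estimate_theta(3), 2 / 3)
  expect_equal(estimate_theta(20), 1 / sum(1 / (1:19)))
  expect_error(estimate_theta(1), "n >= 2")
})

test_that("copying emissions are a faithful-copy/repaint mixture", {
  expect_equal(emission_prob(0, 0, 1, 1), 0.75)
  expect_equal(emission_prob(0, 1, 1, 1), 0.25)
  for (k in c(1, 3, 19)) for (th in c(0.1, 0.28, 2)) {
    expect_equal(emission_prob(1, 1, k, th) + emission_prob(1, 0, k, th), 1)
  }
  # theta -> 0 is perfect copying
  expect_equal(emission_prob(1, 1, 5, 1e-12), 1, tolerance = 1e-11)
})

test_that("crossover chain freezes inside tracts and mixes outside", {
  expect_equal(crossover_transition(4, 1, 2, 2, 2, g_next = 3), 1)
  expect_equal(crossover_transition(4, 1, 2, 2, 3, g_next = 3), 0)
  expect_equal(crossover_transition(4, 1, 0, 2, 2, g_next = NA), 1)
  p <- exp(-0.25)
  expect_equal(crossover_transition(2, 0.5, 1, 1, 1, NA), p + (1 - p) / 2)
})

test_that("conversion chain matches its closed forms and degenerate limits", {
  # gamma = 0: chain inert in the empty state
  expect_equal(conversion_transition(3, 2, 0, 0, NA, NA), 1)
  expect_equal(conversion_transition(3, 2, 0, 0, NA, 1), 0)
  # d = 0: identity
  expect_equal(conversion_transition(3, 0, 2, 0.5, NA, NA), 1)
  expect_equal(conversion_transition(3, 0, 2, 0.5, 2, 2), 1)
  expect_equal(conversion_transition(3, 0, 2, 0.5, 2, NA), 0)
  # competing-risks closed form
  expect_equal(conversion_transition(2, 0.25, 2, 0.5, 1, NA),
               exp(-0.25) * (1 - exp(-0.5)))
  expect_error(conversion_transition(2, 1, 2, 0, 1, NA), "lam")
})

test_that("all transition kernels are row-stochastic across the grid", {
  for (k in c(1, 2, 7, 25)) for (d in c(0, 0.3, 20)) {
    for (pars in list(c(0, 0, 0), c(1, 0.5, 0.3), c(10, 20, 2))) {
      rho <- pars[1]; gamma <- pars[2]; lam <- pars[3]
      gs <- c(NA, seq_len(k))
      for (fg in gs) {
        row <- vapply(gs, function(tg)
          conversion_transition(k, d, gamma, lam, fg, tg), 1.0)
        expect_equal(sum(row), 1, tolerance = 1e-12)
      }
      for (fx in unique(c(1L, k))) for (gn in c(NA, 1L)) {
        row <- vapply(seq_len(k), function(tx)
          crossover_transition(k, d, rho, fx, tx, gn), 1.0)
        expect_equal(sum(row), 1, tolerance = 1e-12)
      }
      expect_equal(sum(initial_state_probs(k, rho, gamma, lam)), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("initial distribution balances tract initiation and termination", {
  p <- initial_state_probs(3, gamma = 0, lam = 0)
  expect_equal(p[, 1], rep(1 / 3, 3))
  expect_equal(initial_state_probs(1, gamma = 1, lam = 1)[1, 1], 0.5)
})

test_that("forward algorithm equals exhaustive path enumeration (k<=3, S<=4)", {
  expect_equal(conditional_log_prob(0, matrix(0, 1, 1), 5, 1, 1, 0.5,
                                    theta_hat = 1), log(0.75))
  set.seed(21)
  for (i in 1:8) {
    k <- sample(1:3, 1); S <- sample(1:4, 1)
    inst <- rand_instance(k, S)
    rho <- runif(1, 0, 2); gamma <- runif(1, 0, 3); lam <- runif(1, 0.1, 1)
    th <- estimate_theta(k + 1)
    expect_equal(
      conditional_log_prob(inst$target, inst$panel, inst$pos, rho, gamma,
                           lam, th),
      oracle_conditional(inst$target, inst$panel, inst$pos, rho, gamma,
                         lam, th),
      tolerance = 1e-10)
  }
})

test_that("forward algorithm matches an independent matrix-product pass", {
  set.seed(22)
  for (i in 1:3) {
    inst <- rand_instance(8, 12, Lmax = 20)
    rho <- runif(1, 0, 2); gamma <- runif(1, 0, 3); lam <- runif(1, 0.1, 1)
    th <- estimate_theta(9)
    expect_equal(
      conditional_log_prob(inst$target, inst$panel, inst$pos, rho, gamma,
                           lam, th),
      matrix_forward(inst$target, inst$panel, inst$pos, rho, gamma, lam, th),
      tolerance = 1e-10)
  }
})

test_that("gamma = 0 collapses the interleaved HMM to crossover-only", {
  set.seed(23)
  for (i in 1:50) {
    k <- sample(1:6, 1); S <- sample(1:8, 1)
    inst <- rand_instance(k, S)
    rho <- runif(1, 0, 3)
    th <- estimate_theta(k + 1)
    expect_equal(
      conditional_log_prob(inst$target, inst$panel, inst$pos, rho, 0, 0, th),
      conditional_log_prob_crossover_only(inst$target, inst$panel, inst$pos,
                                          rho, th),
      tolerance = 1e-10)
  }
})

test_that("conditional probability is invariant to panel labelling", {
  set.seed(24)
  inst <- rand_instance(6, 10)
  th <- estimate_theta(7)
  base <- conditional_log_prob(inst$target, inst$panel, inst$pos, 1, 0.8,
                               0.4, th)
  for (i in 1:5) {
    perm <- sample(6)
    expect_equal(conditional_log_prob(inst$target,
                                      inst$panel[perm, , drop = FALSE],
                                      inst$pos, 1, 0.8, 0.4, th),
                 base, tolerance = 1e-12)
  }
})

test_that("an identical panel copy of the target never lowers its probability", {
  set.seed(25)
  for (i in 1:10) {
    k <- sample(1:5, 1); S <- sample(2:8, 1)
    inst <- rand_instance(k, S)
    th <- 0.3  # held fixed so only the panel changes
    base <- conditional_log_prob(inst$target, inst$panel, inst$pos,
                                 0.8, 0.6, 0.4, th)
    grown <- rbind(inst$panel, inst$target)
    expect_gte(conditional_log_prob(inst$target, grown, inst$pos,
                                    0.8, 0.6, 0.4, th), base - 1e-12)
  }
})
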