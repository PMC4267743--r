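test_that("simulation is reproducible and parameter bookkeeping holds", {
  h1 <- sim_haplotypes(n = 6, L = 10, theta = 1, rho = 0.5, gamma = 0,
                       seed = 71)
  h2 <- sim_haplotypes(n = 6, L = 10, theta = 1, rho = 0.5, gamma = 0,
                       seed = 71)
  expect_identical(h1$alleles, h2$alleles)
  expect_identical(h1$positions, h2$positions)
  h3 <- sim_haplotypes(n = 6, L = 10, theta = 1, rho = 0.5, rate_ratio = 5,
                       lam = 0.5, seed = 72)
  expect_equal(attr(h3, "sim_params")$gamma, 2.5)
  expect_error(sim_genealogy(6, 10, gamma = 1, lam = 0), "lam")
  expect_error(sim_genealogy(6, 10, rho = 5, max_events = 3), "event cap")
})

test_that("without recombination the whole region shares one Kingman tree", {
  set.seed(73)
  g <- sim_genealogy(8, 20)
  expect_identical(nrow(g$intervals), 1L)
  expect_equal(unname(g$intervals[1, c("left", "right")]), c(0, 20))
  tr <- marginal_tree(g, 10)
  expect_s3_class(tr, "phylo")
  expect_identical(ape::Ntip(tr), 8L)
  expect_identical(tr$Nnode, 7L)
  expect_true(ape::is.binary(tr))
})

test_that("every marginal tree carries n leaves and n-1 coalescences", {
  set.seed(74)
  g <- sim_genealogy(7, 20, rho = 1, gamma = 1, lam = 0.5)
  expect_gt(nrow(g$intervals), 1)  # recombination fragments the region
  expect_equal(unname(g$intervals[1, "left"]), 0)
  expect_equal(unname(g$intervals[nrow(g$intervals), "right"]), 20)
  expect_true(all(diff(as.vector(g$intervals[, "left"])) > 0))
  for (i in seq_len(nrow(g$intervals))) {
    expect_identical(g$nodes$nleaves[g$intervals[i, "root"]], 7L)
    mid <- mean(g$intervals[i, c("left", "right")])
    tr <- marginal_tree(g, mid)
    expect_identical(ape::Ntip(tr), 7L)
    expect_identical(tr$Nnode, 6L)
  }
})

test_that("pair coalescence times and diversity match Kingman expectations", {
  set.seed(75)
  heights <- replicate(800, {
    g <- sim_genealogy(2, 20, rho = 0.5, gamma = 0.5, lam = 0.5)
    g$nodes$time[g$intervals[1, "root"]]
  })
  expect_lt(abs(mean(heights) - 1), 3 * sd(heights) / sqrt(800))

  set.seed(76)
  pis <- replicate(400, {
    h <- sim_haplotypes(2, 20, theta = 1)
    sum(h$alleles[1, ] != h$alleles[2, ])
  })
  expect_lt(abs(mean(pis) - 20), 3 * sd(pis) / sqrt(400))
})

test_that("segregating sites follow Watterson's expectation", {
  set.seed(77)
  S <- replicate(300, ncol(sim_haplotypes(10, 20, theta = 1)$alleles))
  expect_lt(abs(mean(S) - 20 * sum(1 / (1:9))), 3 * sd(S) / sqrt(300))
  expect_identical(ncol(sim_haplotypes(5, 20, theta = 0, seed = 1)$alleles),
                   0L)
})

test_that("conversion tract lengths are exponential with mean lambda", {
  set.seed(78)
  tracts <- c()
  while (length(tracts) < 2000)
    tracts <- c(tracts,
                sim_genealogy(5, 20, gamma = 2, lam = 0.5)$tract_lengths)
  expect_lt(abs(mean(tracts) - 0.5), 0.05)
  expect_gt(stats::ks.test(tracts, "pexp", rate = 2)$p.value, 0.01)
})

test_that("conversion-only histories match an established coalescent simulator", {
  # cross-simulator oracle: msprime at identical scaled rates
  script <- "
import msprime, numpy as np
S = []; pi = []
for rep in range(250):
    ts = msprime.sim_ancestry(samples=10, ploidy=1, population_size=1,
        sequence_length=20000,
        gene_conversion_rate=2.5/2000.0, gene_conversion_tract_length=500,
        random_seed=rep + 1)
    mts = msprime.sim_mutations(ts, rate=1.0/2000.0, random_seed=rep + 1,
                                discrete_genome=False)
    S.append(mts.num_sites)
    pi.append(mts.diversity(span_normalise=False))
print(np.mean(S), np.std(S), np.mean(pi), np.std(pi))
"
  out <- suppressWarnings(system2("python", "-", input = script,
                                  stdout = TRUE, stderr = TRUE))
  vals <- suppressWarnings(as.numeric(strsplit(tail(out, 1), "\\s+")[[1]]))
  expect_false(anyNA(vals))
  set.seed(79)
  sims <- replicate(250, {
    h <- sim_haplotypes(10, 20, theta = 1, gamma = 2.5, lam = 0.5)
    c(S = ncol(h$alleles), pi = mean(stats::dist(h$alleles,
                                                 method = "manhattan")))
  })
  se_S <- sqrt(vals[2]^2 / 250 + var(sims["S", ]) / 250)
  se_pi <- sqrt(vals[4]^2 / 250 + var(sims["pi", ]) / 250)
  expect_lt(abs(mean(sims["S", ]) - vals[1]), 4 * se_S)
  expect_lt(abs(mean(sims["pi", ]) - vals[3]), 4 * se_pi)
})
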