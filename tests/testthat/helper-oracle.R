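# Independent oracles for the copying HMM, built from the exported
# single-step probability functions, never from the forward kernels.

# brute-force sum over all (k(k+1))^S hidden paths
oracle_conditional <- function(target, panel, positions, rho, gamma, lam,
                               theta) {
  k <- nrow(panel); S <- ncol(panel)
  gs <- c(NA, seq_len(k))
  st <- expand.grid(x = seq_len(k), gi = seq_len(k + 1))
  ns <- nrow(st)
  init <- initial_state_probs(k, rho, gamma, lam)
  total <- 0
  idx <- rep(1L, S)
  repeat {
    p <- 1
    for (j in seq_len(S)) {
      g <- gs[st$gi[idx[j]]]
      x <- st$x[idx[j]]
      donor <- if (is.na(g)) x else g
      if (j == 1) p <- p * init[x, st$gi[idx[j]]]
      else {
        d <- positions[j] - positions[j - 1]
        gprev <- gs[st$gi[idx[j - 1]]]
        p <- p * conversion_transition(k, d, gamma, lam, gprev, g) *
          crossover_transition(k, d, rho, st$x[idx[j - 1]], x, g)
      }
      p <- p * emission_prob(target[j], panel[donor, j], k, theta)
      if (p == 0) break
    }
    total <- total + p
    j <- 1L
    while (j <= S && idx[j] == ns) { idx[j] <- 1L; j <- j + 1L }
    if (j > S) break
    idx[j] <- idx[j] + 1L
  }
  log(total)
}

# moderate-size independent forward pass via dense transition-matrix products
matrix_forward <- function(target, panel, positions, rho, gamma, lam, theta) {
  k <- nrow(panel); S <- ncol(panel)
  gs <- c(NA, seq_len(k))
  st <- expand.grid(x = seq_len(k), gi = seq_len(k + 1))
  donor <- ifelse(is.na(gs[st$gi]), st$x, gs[st$gi])
  a <- as.vector(initial_state_probs(k, rho, gamma, lam)) *
    emission_prob(target[1], panel[cbind(donor, 1)], k, theta)
  ll <- log(sum(a)); a <- a / sum(a)
  if (S > 1) for (j in 2:S) {
    d <- positions[j] - positions[j - 1]
    Tm <- outer(seq_len(nrow(st)), seq_len(nrow(st)),
                Vectorize(function(i, l)
                  conversion_transition(k, d, gamma, lam, gs[st$gi[i]],
                                        gs[st$gi[l]]) *
                  crossover_transition(k, d, rho, st$x[i], st$x[l],
                                      gs[st$gi[l]])))
    a <- as.vector(a %*% Tm) *
      emission_prob(target[j], panel[cbind(donor, j)], k, theta)
    ll <- ll + log(sum(a)); a <- a / sum(a)
  }
  ll
}

rand_instance <- function(k, S, Lmax = 10) {
  list(panel = matrix(sample(0:1, k * S, TRUE), k, S),
       target = sample(0:1, S, TRUE),
       pos = sort(runif(S, 0, Lmax)))
}

# deterministic 0/1 matrix with a prescribed SNP count, for segmentation and
# io tests
toy_haplotypes <- function(n, S, L = S) {
  set.seed(S * 1000L + n)
  haplotypes(matrix(sample(0:1, n * S, TRUE), n, S),
             positions = sort(runif(S, 0, L)), region_length = L)
}
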