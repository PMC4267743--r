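#' Log probability of the first haplotype
#'
#' The leading factor of the PAC product uses a uniform allele model,
#' \eqn{S \log(1/2)}: it carries no information about the recombination
#' parameters and cancels exactly in likelihood-ratio statistics.
#'
#' @param S number of segregating sites (>= 1).
#' @return \code{S * log(0.5)}.
#' @export
first_haplotype_log_prob <- function(S) {
  S <- as.integer(S)
  if (is.na(S) || S < 1) stop("need S >= 1")
  S * log(0.5)
}

#' PAC surrogate log-likelihood
#'
#' The product-of-approximate-conditionals surrogate for the joint haplotype
#' likelihood: \eqn{\log \hat\pi(h_1) + \sum_{k=1}^{n-1}
#' \log\hat\pi(h_{k+1} \mid h_1,\dots,h_k)}, each conditional evaluated by
#' the interleaved copying HMM (\code{\link{conditional_log_prob}}) with a
#' common per-site mutation parameter \code{\link{estimate_theta}(n)}. The
#' value depends on the conditioning order of the haplotypes; by default the
#' input row order is used (deterministic), or the mean over random
#' permutations can be requested.
#'
#' @param x a \code{\link{haplotypes}} object with n >= 2 and S >= 1.
#' @param rho,gamma,lam model rates (per kb, per kb, kb).
#' @param order \code{"fixed"} (input row order) or \code{"averaged"}
#'   (mean log-likelihood over \code{n_orders} random permutations).
#' @param n_orders number of permutations when \code{order = "averaged"}.
#' @param order_seed integer seed for the permutations.
#' @param crossover_only force the crossover-only model (gamma, lam ignored).
#' @return the scalar log-likelihood.
#' @export
pac_log_likelihood <- function(x, rho, gamma = 0, lam = 0,
                               order = c("fixed", "averaged"),
                               n_orders = 10L, order_seed = 1L,
                               crossover_only = FALSE) {
  check_likelihood_input(x)
  order <- match.arg(order)
  pars <- c(rho, gamma, lam)
  if (any(!is.finite(pars)) || rho < 0 || gamma < 0)
    stop("rates must be finite and nonnegative")
  if (gamma > 0 && lam <= 0) stop("lam must be > 0 when gamma > 0")
  n <- n_hap(x)
  theta_hat <- estimate_theta(n)
  H <- as_int_matrix(x$alleles)
  eval_one <- function(perm)
    .pac_loglik_cpp(H[perm, , drop = FALSE], x$positions, rho, gamma, lam,
                    theta_hat, crossover_only, TRUE)
  if (order == "fixed") return(eval_one(seq_len(n)))
  if (n_orders < 1) stop("n_orders must be >= 1")
  perms <- local({
    set.seed(as.integer(order_seed))
    replicate(n_orders, sample.int(n), simplify = FALSE)
  })
  mean(vapply(perms, eval_one, numeric(1)))
}

#' Log prior density of the mean conversion tract length
#'
#' The tract-length prior places \eqn{\log_{10}\lambda \sim N(-0.5, 0.4^2)},
#' chosen so that \eqn{P(\lambda \in [0.05, 2]\,\mathrm{kb}) = 95\%}, the
#' range tract lengths typically occupy. On the \eqn{\lambda} scale this is
#' a log-normal density (change of variables through \eqn{\ln 10}).
#'
#' @param lam tract length in kb; the density is \code{-Inf} for
#'   \code{lam <= 0}.
#' @param mu,sigma mean and sd of the normal on \eqn{\log_{10}\lambda}.
#' @return log density (vectorised over \code{lam}).
#' @export
log_prior_lambda <- function(lam, mu = -0.5, sigma = 0.4) {
  out <- rep(-Inf, length(lam))
  ok <- is.finite(lam) & lam > 0
  l <- lam[ok]
  out[ok] <- -log(l * log(10) * sigma * sqrt(2 * pi)) -
    (log10(l) - mu)^2 / (2 * sigma^2)
  out
}

#' Log posterior objective of the copying model
#'
#' The objective maximised when fitting: the PAC log-likelihood plus the
#' log tract-length prior, \eqn{\log f(\lambda) + \log\ell(\rho,\gamma,\lambda)}.
#' When \code{gamma = 0} the model has no tract-length parameter and the
#' prior term is omitted, leaving the crossover-only PAC log-likelihood.
#'
#' @inheritParams pac_log_likelihood
#' @return scalar log posterior (up to the normalising constant of the
#'   posterior, which is irrelevant for maximisation).
#' @export
log_posterior <- function(x, rho, gamma = 0, lam = 0,
                          order = c("fixed", "averaged"),
                          n_orders = 10L, order_seed = 1L) {
  order <- match.arg(order)
  ll <- pac_log_likelihood(x, rho, gamma, lam, order = order,
                           n_orders = n_orders, order_seed = order_seed)
  if (gamma > 0) ll + log_prior_lambda(lam) else ll
}
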