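#' Per-site copying mutation parameter
#'
#' The PAC copying model's per-site mutation parameter,
#' \eqn{\hat\theta = (\sum_{i=1}^{n-1} 1/i)^{-1}}, a function of the sample
#' size only. It controls how often the copied allele is "repainted" instead
#' of faithfully copied.
#'
#' @param n sample size (total number of haplotypes), \code{n >= 2}.
#' @return the scalar \eqn{\hat\theta}.
#' @examples
#' estimate_theta(2)   # 1
#' estimate_theta(3)   # 2/3
#' @export
estimate_theta <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("need n >= 2")
  1 / sum(1 / seq_len(n - 1))
}

#' Copying emission probability
#'
#' Probability of observing allele \code{allele} at a site given the donor
#' haplotype carries \code{donor_allele}, with \code{k} haplotypes in the
#' copying panel: a faithful copy with probability \eqn{k/(k+\hat\theta)},
#' otherwise a uniform repaint over the two alleles.
#'
#' @param allele,donor_allele alleles in \{0, 1\}.
#' @param k panel size (number of haplotypes already observed).
#' @param theta_hat per-site mutation parameter, see
#'   \code{\link{estimate_theta}}.
#' @return emission probability.
#' @export
emission_prob <- function(allele, donor_allele, k, theta_hat) {
  stopifnot(all(allele %in% 0:1), all(donor_allele %in% 0:1))
  base <- (theta_hat / (k + theta_hat)) / 2
  ifelse(allele == donor_allele, k / (k + theta_hat) + base, base)
}

#' Crossover-chain transition probability
#'
#' One step of the crossover (donor) chain of the interleaved copying HMM.
#' When the next site lies inside a conversion tract (\code{g_next} not
#' \code{NA}) the crossover chain is frozen: probability is the indicator of
#' staying put. Outside tracts the chain jumps as a Poisson process with
#' rate \eqn{\rho} per kb (scaled by 1/k): with \eqn{p = e^{-\rho d/k}} the
#' chain stays with probability \eqn{p + (1-p)/k} and moves to any specific
#' other donor with probability \eqn{(1-p)/k}.
#'
#' @param k panel size; donors are indexed 1..k.
#' @param d inter-SNP distance in kb (>= 0).
#' @param rho crossover rate per kb.
#' @param from_x,to_x donor indices in 1..k.
#' @param g_next conversion-chain state at the next site: \code{NA} for the
#'   empty (no-tract) state, otherwise a donor index.
#' @return transition probability.
#' @export
crossover_transition <- function(k, d, rho, from_x, to_x, g_next = NA) {
  stopifnot(from_x >= 1, from_x <= k, to_x >= 1, to_x <= k, d >= 0, rho >= 0)
  if (!is.na(g_next)) return(as.numeric(to_x == from_x))
  p <- exp(-rho * d / k)
  if (to_x == from_x) p + (1 - p) / k else (1 - p) / k
}

#' Conversion-chain transition probability
#'
#' One step of the gene-conversion tract chain. Tract initiation is Poisson
#' with rate \eqn{\gamma} per kb (scaled by 1/k like the crossover chain)
#' and tract termination is Poisson with rate \eqn{1/\lambda}; overlapping
#' conversions are allowed by letting a fresh tract (new donor, uniform
#' over the k panel members) begin inside an ongoing one. With
#' \eqn{c = 1 - e^{-\gamma d/k}} (a new tract covers the next site) and
#' \eqn{e = 1 - e^{-d/\lambda}} (the ongoing tract has ended first):
#' \itemize{
#'   \item empty -> empty: \eqn{1 - c}
#'   \item empty -> donor b: \eqn{c/k}
#'   \item donor a -> donor b (renewal/overlap, any b): \eqn{c/k},
#'         plus \eqn{(1-c)(1-e)} extra mass on b = a (tract continues)
#'   \item donor a -> empty: \eqn{(1-c)\,e}
#' }
#' Rows sum to one exactly, and \eqn{\gamma = 0} freezes the chain in the
#' empty state, collapsing the model onto the crossover-only copying HMM.
#'
#' @inheritParams crossover_transition
#' @param gamma conversion initiation rate per kb.
#' @param lam mean conversion tract length in kb (> 0 when gamma > 0).
#' @param from_g,to_g conversion states: \code{NA} for empty, else donor
#'   index in 1..k.
#' @return transition probability.
#' @export
conversion_transition <- function(k, d, gamma, lam, from_g, to_g) {
  stopifnot(d >= 0, gamma >= 0)
  if (gamma > 0 && (is.na(lam) || lam <= 0))
    stop("lam must be > 0 when gamma > 0")
  cc <- if (gamma > 0) 1 - exp(-gamma * d / k) else 0
  ee <- if (gamma > 0) 1 - exp(-d / lam) else 0
  if (is.na(from_g)) {
    if (is.na(to_g)) 1 - cc else cc / k
  } else {
    if (is.na(to_g)) (1 - cc) * ee
    else cc / k + if (to_g == from_g) (1 - cc) * (1 - ee) else 0
  }
}

#' Initial distribution of the interleaved chains
#'
#' The crossover chain starts uniform over the k donors. The conversion
#' chain starts in the empty state with probability \eqn{1/(1+\gamma\lambda/k)}
#' (the stationary balance of initiation rate \eqn{\gamma/k} and termination
#' rate \eqn{1/\lambda}), otherwise uniform over donors. The joint initial
#' distribution is the product.
#'
#' @inheritParams conversion_transition
#' @param rho crossover rate per kb (unused; accepted for a uniform
#'   parameter interface).
#' @return a \code{k x (k+1)} matrix of initial joint probabilities; column 1
#'   is the empty conversion state, column 1+b is conversion donor b.
#' @export
initial_state_probs <- function(k, rho = 0, gamma = 0, lam = 0) {
  stopifnot(k >= 1)
  odds <- if (gamma > 0) gamma * lam / k else 0
  p_empty <- 1 / (1 + odds)
  px <- rep(1 / k, k)
  cbind(px * p_empty, matrix(px * (1 - p_empty) / k, k, k))
}

as_int_matrix <- function(m) { m <- as.matrix(m); storage.mode(m) <- "integer"; m }

#' Log conditional copying probability of one haplotype
#'
#' Forward-algorithm evaluation of \eqn{\log \hat\pi(h \mid panel)} under the
#' interleaved crossover/conversion copying HMM with joint hidden states
#' (crossover donor, conversion state), computed in scaled arithmetic for
#' numerical stability. With \code{gamma = 0} this reduces exactly to the
#' crossover-only copying model.
#'
#' @param target integer vector of S alleles in \{0,1\}.
#' @param panel k x S matrix of previously observed haplotypes.
#' @param positions SNP positions in kb (length S, nondecreasing).
#' @param rho,gamma,lam model rates, see \code{\link{conversion_transition}}.
#' @param theta_hat per-site mutation parameter; defaults to
#'   \code{estimate_theta(k + 1)}.
#' @return the scalar log probability.
#' @export
conditional_log_prob <- function(target, panel, positions, rho, gamma, lam,
                                 theta_hat = NULL) {
  panel <- as_int_matrix(panel)
  k <- nrow(panel); S <- ncol(panel)
  if (S < 1) stop("need at least one site")
  if (length(target) != S || length(positions) != S)
    stop("target, panel columns and positions must have equal length")
  pars <- c(rho, gamma, lam)
  if (any(!is.finite(pars)) || rho < 0 || gamma < 0)
    stop("rates must be finite and nonnegative")
  if (gamma > 0 && lam <= 0) stop("lam must be > 0 when gamma > 0")
  if (is.null(theta_hat)) theta_hat <- estimate_theta(k + 1)
  .fwd_joint_cpp(as.integer(target), panel, as.numeric(positions),
                 rho, gamma, lam, theta_hat)
}

#' @rdname conditional_log_prob
#' @export
conditional_log_prob_crossover_only <- function(target, panel, positions, rho,
                                                theta_hat = NULL) {
  panel <- as_int_matrix(panel)
  k <- nrow(panel); S <- ncol(panel)
  if (S < 1) stop("need at least one site")
  if (length(target) != S || length(positions) != S)
    stop("target, panel columns and positions must have equal length")
  if (!is.finite(rho) || rho < 0) stop("rho must be finite and nonnegative")
  if (is.null(theta_hat)) theta_hat <- estimate_theta(k + 1)
  .fwd_cross_cpp(as.integer(target), panel, as.numeric(positions),
                 rho, theta_hat)
}
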