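#' Simulate an ancestral recombination graph with gene conversion
#'
#' Event-driven back-in-time simulation for a sample of \code{n} haplotypes
#' over a region of \code{L} kb: pairwise coalescence at rate
#' \eqn{k(k-1)/2}, per-lineage crossover at rate \eqn{\rho L/2} with a
#' uniform breakpoint, and per-lineage gene conversion at rate
#' \eqn{\gamma L/2} with a uniform tract start and an exponential tract
#' length of mean \eqn{\lambda} kb (tracts may cross the region boundary and
#' are truncated). Rates are population-scaled per kb; time is in coalescent
#' units. Events may fall in non-ancestral material; resulting empty
#' lineages are pruned, which leaves the sample distribution unchanged.
#'
#' @param n sample size (>= 2).
#' @param L region length in kb.
#' @param rho crossover rate per kb.
#' @param gamma gene-conversion initiation rate per kb.
#' @param lam mean conversion tract length in kb (> 0 when gamma > 0).
#' @param max_events safety cap on the number of events before aborting
#'   with an error suggesting smaller rates.
#' @return an object of class \code{"genealogy"}: the breakpoint-indexed
#'   marginal trees as an \code{intervals} matrix (left, right, root node),
#'   the node tables (\code{time}, children, leaf counts), the drawn
#'   conversion tract lengths, and the event count. Uses the current RNG
#'   stream; seed management is the caller's.
#' @seealso \code{\link{drop_mutations}}, \code{\link{marginal_tree}},
#'   \code{\link{sim_haplotypes}}
#' @export
sim_genealogy <- function(n, L, rho = 0, gamma = 0, lam = 0,
                          max_events = 1e6) {
  stopifnot(n >= 2, L > 0, rho >= 0, gamma >= 0)
  if (gamma > 0 && lam <= 0) stop("lam must be > 0 when gamma > 0")
  raw <- .coalsim_cpp(as.integer(n), L, rho, gamma, lam, 0, max_events)
  as_genealogy(raw, as.integer(n), L)
}

as_genealogy <- function(raw, n, L) {
  structure(list(n = n, L = L,
                 intervals = raw$intervals,
                 nodes = list(time = raw$time, c1 = raw$c1, c2 = raw$c2,
                              nleaves = raw$nleaves),
                 tract_lengths = raw$tracts,
                 n_events = as.integer(raw$n_events)),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("genealogy: n=%d over %.4g kb, %d marginal-tree interval(s), %d events\n",
              x$n, x$L, nrow(x$intervals), x$n_events))
  invisible(x)
}

# all nodes of the subtree under `root`, with each node's branch length to
# its parent (root itself excluded)
subtree_branches <- function(gen, root) {
  nodes <- integer(0); parent_time <- numeric(0)
  stack_n <- root; stack_t <- NA_real_
  tt <- gen$nodes$time; c1 <- gen$nodes$c1; c2 <- gen$nodes$c2
  while (length(stack_n)) {
    v <- stack_n[1]; pt <- stack_t[1]
    stack_n <- stack_n[-1]; stack_t <- stack_t[-1]
    if (!is.na(pt)) { nodes <- c(nodes, v); parent_time <- c(parent_time, pt) }
    if (c1[v] > 0) {
      stack_n <- c(stack_n, c1[v], c2[v])
      stack_t <- c(stack_t, tt[v], tt[v])
    }
  }
  list(nodes = nodes, branch = parent_time - tt[nodes])
}

leaves_under <- function(gen, node) {
  out <- integer(0); stack <- node
  c1 <- gen$nodes$c1; c2 <- gen$nodes$c2
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (c1[v] == 0) out <- c(out, v) else stack <- c(stack, c1[v], c2[v])
  }
  out
}

#' Extract the marginal tree at a position
#'
#' @param gen a \code{\link{sim_genealogy}} result.
#' @param pos position in kb within [0, L).
#' @return an \code{ape} \code{"phylo"} tree with branch lengths in
#'   coalescent units; tip labels are the haplotype indices.
#' @export
marginal_tree <- function(gen, pos) {
  iv <- gen$intervals
  i <- which(iv[, "left"] <= pos & pos < iv[, "right"])
  if (!length(i)) stop("position not covered by any marginal tree interval")
  root <- iv[i[1], "root"]
  tt <- gen$nodes$time; c1 <- gen$nodes$c1; c2 <- gen$nodes$c2
  newick <- function(v, parent_time) {
    br <- sprintf(":%.10g", parent_time - tt[v])
    if (c1[v] == 0) return(paste0(v, br))
    paste0("(", newick(c1[v], tt[v]), ",", newick(c2[v], tt[v]), ")", br)
  }
  txt <- paste0("(", newick(c1[root], tt[root]), ",",
                newick(c2[root], tt[root]), ");")
  ape::read.tree(text = txt)
}

#' Drop infinite-sites mutations onto a simulated genealogy
#'
#' Mutations fall as a Poisson process of rate \eqn{\theta/2} per kb per
#' unit branch length on the marginal trees: each breakpoint interval
#' receives \code{Poisson((theta/2) * width * tree_length)} mutations,
#' placed uniformly on branches and positions; every mutation makes one SNP
#' column carried by the leaves below it. Uses the current RNG stream.
#'
#' @param gen a \code{\link{sim_genealogy}} result.
#' @param theta mutation rate per kb.
#' @return a \code{\link{haplotypes}} object with positions sorted.
#' @export
drop_mutations <- function(gen, theta) {
  stopifnot(inherits(gen, "genealogy"), theta >= 0)
  n <- gen$n
  pos <- numeric(0); cols <- list()
  iv <- gen$intervals
  for (i in seq_len(nrow(iv))) {
    sb <- subtree_branches(gen, iv[i, "root"])
    tlen <- sum(sb$branch)
    width <- iv[i, "right"] - iv[i, "left"]
    nmut <- stats::rpois(1, theta / 2 * width * tlen)
    if (nmut == 0) next
    br <- sample.int(length(sb$nodes), nmut, replace = TRUE,
                     prob = sb$branch)
    p <- stats::runif(nmut, iv[i, "left"], iv[i, "right"])
    for (m in seq_len(nmut)) {
      col <- integer(n)
      col[leaves_under(gen, sb$nodes[br[m]])] <- 1L
      pos <- c(pos, p[m]); cols[[length(cols) + 1L]] <- col
    }
  }
  if (!length(pos))
    return(haplotypes(matrix(0L, n, 0L), numeric(0), gen$L))
  # infinite-sites: distinct uniform draws are a.s. unique; guard regardless
  while (any(duplicated(pos))) pos[duplicated(pos)] <- pos[duplicated(pos)] +
      1e-9 * gen$L
  ord <- order(pos)
  haplotypes(do.call(cbind, cols)[, ord, drop = FALSE], pos[ord], gen$L)
}

#' Simulate a haplotype sample under the coalescent with gene conversion
#'
#' Convenience wrapper: \code{\link{sim_genealogy}} followed by
#' \code{\link{drop_mutations}}, with optional seeding and the
#' \code{rate_ratio} convenience (\eqn{f = \gamma/\rho}) used in simulation
#' studies.
#'
#' @inheritParams sim_genealogy
#' @param theta mutation rate per kb.
#' @param rate_ratio optional f; when given, \code{gamma = f * rho}.
#' @param seed optional integer seed (\code{set.seed}) for reproducibility.
#' @return a \code{\link{haplotypes}} object; the generating parameters are
#'   attached as attribute \code{"sim_params"}.
#' @examples
#' h <- sim_haplotypes(n = 6, L = 20, theta = 1, rho = 0.5, seed = 1)
#' h
#' @export
sim_haplotypes <- function(n, L, theta, rho = 0, gamma = 0, lam = 0,
                           rate_ratio = NULL, seed = NULL,
                           max_events = 1e6) {
  if (!is.null(rate_ratio)) gamma <- rate_ratio * rho
  stopifnot(n >= 2, L > 0, rho >= 0, gamma >= 0, theta >= 0)
  if (gamma > 0 && lam <= 0) stop("lam must be > 0 when gamma > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  raw <- .coalsim_cpp(as.integer(n), L, rho, gamma, lam, theta, max_events)
  pos <- raw$positions
  # infinite-sites: uniform draws are a.s. distinct; guard regardless
  while (any(duplicated(pos))) pos[duplicated(pos)] <- pos[duplicated(pos)] +
      1e-9 * L
  h <- haplotypes(raw$alleles[, order(pos), drop = FALSE], sort(pos), L)
  attr(h, "sim_params") <- list(n = n, L = L, theta = theta, rho = rho,
                                gamma = gamma, lam = lam, seed = seed)
  h
}
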