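#' Likelihood-ratio statistic for a boundary null
#'
#' Computes \eqn{\Lambda(H) = -2 \{ \sup_{null} \log L - \sup_{full}
#' \log L \}} for one of the two boundary null hypotheses:
#' \describe{
#'   \item{\code{"no-conversion"}}{\eqn{H_0: \gamma = 0}; the null supremum
#'     is the crossover-only PAC likelihood over \eqn{\rho} (no tract-length
#'     prior, since \eqn{\lambda} is not a parameter of that model), the
#'     alternative the full posterior over \eqn{(\rho,\gamma,\lambda)}.}
#'   \item{\code{"no-crossover"}}{\eqn{H_0: \rho = 0}; the null supremum is
#'     over \eqn{(\gamma,\lambda)} at \eqn{\rho = 0} with the prior active.}
#' }
#' Because the null value lies on the boundary of the parameter space (and
#' \eqn{\gamma = 0} and \eqn{\lambda = 0} are not separately identifiable),
#' \eqn{\Lambda} does not follow the usual chi-squared asymptotics; its
#' reference distribution must be built by the parametric bootstrap
#' (\code{\link{rectest}}). \eqn{\Lambda} can come out slightly negative
#' (prior factor and finite optimiser tolerance) and is returned unclamped.
#'
#' @inheritParams recfit
#' @param null which boundary hypothesis.
#' @return an object of class \code{"reclrt"}: \code{lambda_stat},
#'   \code{fit_null}, \code{fit_full}, \code{null}.
#' @export
lrt_statistic <- function(x, null = c("no-conversion", "no-crossover"),
                          order = c("fixed", "averaged"), n_orders = 10L,
                          order_seed = 1L, control = recfit_control()) {
  null <- match.arg(null)
  order <- match.arg(order)
  null_model <- if (null == "no-conversion") "crossover" else "conversion"
  fit0 <- recfit(x, model = null_model, order = order, n_orders = n_orders,
                 order_seed = order_seed, control = control)
  fit1 <- recfit(x, model = "full", order = order, n_orders = n_orders,
                 order_seed = order_seed, control = control)
  structure(list(lambda_stat = -2 * (fit0$objective - fit1$objective),
                 fit_null = fit0, fit_full = fit1, null = null),
            class = "reclrt")
}

#' @export
print.reclrt <- function(x, digits = 4, ...) {
  cat(sprintf("LRT for %s: Lambda(H) = %.*g\n", x$null, digits, x$lambda_stat))
  cat(sprintf("  null objective %.6g (%s fit), full objective %.6g\n",
              x$fit_null$objective, x$fit_null$model, x$fit_full$objective))
  invisible(x)
}

p_from_replicates <- function(lambda_obs, lambda_rep,
                              estimator = c("plain", "add-one")) {
  estimator <- match.arg(estimator)
  hits <- sum(lambda_rep >= lambda_obs)  # ties count toward the null
  if (estimator == "plain") hits / length(lambda_rep)
  else (hits + 1) / (length(lambda_rep) + 1)
}

#' Parametric-bootstrap test for crossover or gene conversion
#'
#' The full testing procedure: (1) compute the observed boundary-null LRT
#' statistic \eqn{\Lambda(H)} (\code{\link{lrt_statistic}}); (2) estimate
#' the nuisance parameters under the null (\eqn{\hat\rho} for the
#' no-conversion test; \eqn{(\hat\gamma,\hat\lambda)} for the no-crossover
#' test); (3) draw \code{B} coalescent samples of the same size and region
#' length from the fitted null, with mutation rate given by the data's
#' Watterson estimate; (4) recompute \eqn{\Lambda} on each replicate;
#' (5) report the proportion of replicates whose statistic reaches the
#' observed one. p = 0 is a possible outcome of the plain estimator; the
#' add-one variant \eqn{(\#+1)/(B+1)} is available.
#'
#' @inheritParams lrt_statistic
#' @param B number of bootstrap replicates (200 is the simulation-study
#'   default; 500 is typical for data analysis).
#' @param seed integer seed; all replicate streams derive from it, making
#'   the p-value bit-reproducible.
#' @param estimator \code{"plain"} (\eqn{\#/B}) or \code{"add-one"}.
#' @param theta optional per-kb mutation rate for the replicates,
#'   overriding the Watterson estimate.
#' @param replicate_control \code{\link{recfit_control}} used for replicate
#'   fits; the default uses a single Nelder-Mead start to keep the
#'   bootstrap affordable (observed-data fits keep the multi-start default).
#' @return an object of class \code{"recboot"}: \code{p_value}, \code{B},
#'   \code{observed} (the \code{"reclrt"}), \code{null_params},
#'   \code{replicate_stats}, \code{seed}, \code{n_warn} (replicate fits
#'   that did not flag convergence; they are retained and counted normally).
#' @examples
#' \donttest{
#' h <- sim_haplotypes(n = 8, L = 10, theta = 1, rho = 1, seed = 7)
#' tst <- rectest(h, null = "no-conversion", B = 20, seed = 1)
#' tst
#' }
#' @export
rectest <- function(x, null = c("no-conversion", "no-crossover"), B = 200L,
                    seed = 1L, order = c("fixed", "averaged"), n_orders = 10L,
                    order_seed = 1L, control = recfit_control(),
                    estimator = c("plain", "add-one"), theta = NULL,
                    replicate_control = NULL) {
  null <- match.arg(null)
  order <- match.arg(order)
  estimator <- match.arg(estimator)
  B <- as.integer(B)
  if (B < 1) stop("need B >= 1")
  obs <- lrt_statistic(x, null = null, order = order, n_orders = n_orders,
                       order_seed = order_seed, control = control)
  null_params <- coef(obs$fit_null)
  if (is.null(theta)) theta <- watterson_theta(x)
  if (is.null(replicate_control))
    replicate_control <- recfit_control(starts = default_starts()[1, ,
                                                                  drop = FALSE],
                                        maxit = control$maxit,
                                        abstol = control$abstol,
                                        lower = control$lower,
                                        upper = control$upper)
  n <- n_hap(x); L <- x$region_length
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  lambda_rep <- numeric(B)
  n_warn <- 0L
  for (b in seq_len(B)) {
    s <- rep_seeds[b]
    repeat {
      hb <- sim_haplotypes(n, L, theta, rho = null_params["rho"],
                           gamma = null_params["gamma"],
                           lam = null_params["lam"], seed = s)
      if (n_snp(hb) >= 2) break
      s <- sample.int(.Machine$integer.max - 1L, 1)  # near-empty replicate
    }
    lb <- lrt_statistic(hb, null = null, order = order, n_orders = n_orders,
                        order_seed = order_seed, control = replicate_control)
    if (!lb$fit_full$converged || !lb$fit_null$converged)
      n_warn <- n_warn + 1L
    lambda_rep[b] <- lb$lambda_stat
  }
  structure(list(p_value = p_from_replicates(obs$lambda_stat, lambda_rep,
                                             estimator),
                 B = B, observed = obs, null_params = null_params,
                 replicate_stats = lambda_rep, seed = seed, theta = theta,
                 estimator = estimator, n_warn = n_warn, null = null),
            class = "recboot")
}

#' @export
print.recboot <- function(x, digits = 4, ...) {
  cat(sprintf("Parametric bootstrap test (%s), B = %d\n", x$null, x$B))
  cat(sprintf("  observed Lambda(H) = %.*g\n", digits,
              x$observed$lambda_stat))
  cat("  null nuisance fit:",
      paste(sprintf("%s = %.4g", names(x$null_params), x$null_params),
            collapse = ", "), "\n")
  cat(sprintf("  p-value = %.4g (%s estimator)\n", x$p_value, x$estimator))
  if (x$n_warn)
    cat(sprintf("  note: %d replicate fit(s) without a convergence flag\n",
                x$n_warn))
  invisible(x)
}

#' Segment-wise bootstrap tests across a locus
#'
#' Applies \code{\link{rectest}} to each overlapping window of a locus
#' (\code{\link{segment_haplotypes}}) and tabulates the p-values the way
#' locus scans are reported: one row per segment with its physical length
#' and the p-value for each requested null.
#'
#' @inheritParams rectest
#' @param window,overlap segmentation, see \code{\link{segment_haplotypes}}.
#' @param nulls which boundary nulls to test.
#' @return a data.frame with columns \code{segment}, \code{snps},
#'   \code{length_kb} and one p-value column per null.
#' @export
rectest_segments <- function(x, window = 20L, overlap = 15L,
                             nulls = c("no-conversion", "no-crossover"),
                             B = 500L, seed = 1L, ...) {
  segs <- segment_haplotypes(x, window = window, overlap = overlap)
  nulls <- match.arg(nulls, several.ok = TRUE)
  out <- data.frame(segment = paste0("s", seq_along(segs)),
                    snps = vapply(segs, n_snp, 1L),
                    length_kb = vapply(segs, function(s) s$region_length,
                                       1.0))
  for (nl in nulls) {
    out[[paste0("p_", gsub("-", "_", nl))]] <-
      vapply(seq_along(segs), function(i)
        rectest(segs[[i]], null = nl, B = B,
                seed = seed + i, ...)$p_value, 1.0)
  }
  out
}
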