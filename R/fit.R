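#' Control parameters for model fitting
#'
#' Search is performed in log10-transformed coordinates inside finite boxes:
#' rho and gamma in [1e-4, 1e3] per kb, lambda in [1e-3, 1e2] kb. Hitting a
#' bound is reported, not an error. The three deterministic starting points
#' for the full model are (rho, gamma, lambda) = (1, 1, 0.3162),
#' (0.1, 1, 0.3162) and (1, 0.1, 0.3162), the tract length starting at the
#' prior median.
#'
#' @param starts matrix of starting values in natural units (one row per
#'   start, columns rho, gamma, lambda); \code{NULL} for the defaults.
#' @param maxit maximum objective evaluations per start.
#' @param abstol absolute objective tolerance for Nelder-Mead.
#' @param lower,upper box bounds in log10 units for (rho, gamma, lambda).
#' @return a list of class \code{"recfit_control"}.
#' @export
recfit_control <- function(starts = NULL, maxit = 500L, abstol = 1e-5,
                           lower = c(-4, -4, -3), upper = c(3, 3, 2)) {
  if (!is.null(starts)) {
    starts <- as.matrix(starts)
    if (ncol(starts) != 3) stop("starts must have 3 columns (rho, gamma, lam)")
  }
  structure(list(starts = starts, maxit = as.integer(maxit), abstol = abstol,
                 lower = lower, upper = upper),
            class = "recfit_control")
}

default_starts <- function() {
  rbind(c(1, 1, 10^-0.5), c(0.1, 1, 10^-0.5), c(1, 0.1, 10^-0.5))
}

# penalised objective in clamped log10 coordinates; counts evaluations
make_box_obj <- function(fn, lower, upper, counter) {
  function(u) {
    uc <- pmin(pmax(u, lower), upper)
    counter$n <- counter$n + 1L
    val <- fn(uc)
    if (!is.finite(val)) return(-1e10)
    val - 1e3 * sum((u - uc)^2)
  }
}

#' Fit the recombination copying model to haplotype data
#'
#' Maximum a posteriori / maximum likelihood estimation of the
#' population-scaled crossover rate \eqn{\rho}, gene-conversion initiation
#' rate \eqn{\gamma}, and mean conversion tract length \eqn{\lambda} under
#' the PAC copying likelihood with interleaved crossover/conversion chains.
#' Three nested models are available:
#' \describe{
#'   \item{\code{"full"}}{all three parameters free; the tract-length prior
#'     is part of the objective (\code{\link{log_posterior}}); multi-start
#'     Nelder-Mead in log10 coordinates.}
#'   \item{\code{"crossover"}}{\eqn{\gamma = \lambda = 0} fixed: the
#'     crossover-only PAC model, the null of the no-gene-conversion test;
#'     one-dimensional golden-section/Brent search over \eqn{\log_{10}\rho}.}
#'   \item{\code{"conversion"}}{\eqn{\rho = 0} fixed: conversion-only model
#'     (prior active), the null of the no-crossover test; two-dimensional
#'     Nelder-Mead.}
#' }
#'
#' @param x a \code{\link{haplotypes}} object (n >= 2, S >= 2).
#' @param model which parameterisation to fit.
#' @param order,n_orders,order_seed conditioning-order policy passed to
#'   \code{\link{pac_log_likelihood}}.
#' @param control a \code{\link{recfit_control}} list.
#' @return an object of class \code{"recfit"} with components
#'   \code{params} (named raw estimates; gamma exactly as attained, even at
#'   the box bound), \code{objective}, \code{converged}, \code{n_eval},
#'   \code{starts} (per-start table), \code{boundary} (which parameters sit
#'   on a box bound), \code{model}, \code{theta_hat}, and the data summary.
#'   \code{coef()} maps a gamma at the lower box bound to 0 (no measurable
#'   conversion signal); the raw value stays in \code{$params}.
#' @examples
#' h <- sim_haplotypes(n = 8, L = 10, theta = 1, rho = 1, seed = 42)
#' f <- recfit(h, model = "crossover")
#' coef(f)
#' @export
recfit <- function(x, model = c("full", "crossover", "conversion"),
                   order = c("fixed", "averaged"), n_orders = 10L,
                   order_seed = 1L, control = recfit_control()) {
  check_likelihood_input(x)
  if (n_snp(x) < 2) stop("need at least 2 segregating sites to fit")
  model <- match.arg(model)
  order <- match.arg(order)
  ll_args <- list(order = order, n_orders = n_orders, order_seed = order_seed)
  lo <- control$lower; up <- control$upper
  counter <- new.env(); counter$n <- 0L

  if (model == "crossover") {
    fn <- function(u) do.call(pac_log_likelihood,
                              c(list(x, rho = 10^u[1], crossover_only = TRUE),
                                ll_args))
    obj <- make_box_obj(fn, lo[1], up[1], counter)
    opt <- stats::optimize(obj, c(lo[1], up[1]), maximum = TRUE, tol = 1e-4)
    u_best <- opt$maximum; val <- opt$objective
    params <- c(rho = 10^u_best, gamma = 0, lam = 0)
    boundary <- c(rho = min(u_best - lo[1], up[1] - u_best) < 1e-3,
                  gamma = FALSE, lam = FALSE)
    starts_tab <- data.frame(rho = NA, gamma = NA, lam = NA,
                             objective = val, converged = TRUE)
    converged <- TRUE
  } else {
    free <- if (model == "full") 1:3 else 2:3
    starts <- control$starts
    if (is.null(starts)) {
      # the conversion-only surface is often bimodal (moderate-gamma/long-
      # tract vs high-gamma/short-tract); its null fit gets a high-rate start
      starts <- if (model == "conversion")
        rbind(c(0, 1, 10^-0.5), c(0, 0.1, 10^-0.5), c(0, 10, 10^-0.5))
      else default_starts()
    }
    starts <- starts[!duplicated(starts[, free, drop = FALSE]), , drop = FALSE]
    fn <- function(u) {
      par <- c(0, 0, 0); par[free] <- 10^u
      if (model == "conversion") par[1] <- 0
      do.call(log_posterior, c(list(x, rho = par[1], gamma = par[2],
                                    lam = par[3]), ll_args))
    }
    obj <- make_box_obj(fn, lo[free], up[free], counter)
    runs <- lapply(seq_len(nrow(starts)), function(i) {
      u0 <- log10(starts[i, free])
      o <- stats::optim(u0, obj, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = control$maxit,
                                       abstol = control$abstol))
      list(u = pmin(pmax(o$par, lo[free]), up[free]), value = o$value,
           converged = o$convergence == 0L)
    })
    vals <- vapply(runs, `[[`, numeric(1), "value")
    best <- runs[[which.max(vals)]]
    u_best <- best$u
    val <- best$value
    converged <- any(vapply(runs, `[[`, TRUE, "converged"))
    params <- c(rho = 0, gamma = 0, lam = 0)
    params[free] <- 10^u_best
    names(params) <- c("rho", "gamma", "lam")
    boundary <- c(rho = FALSE, gamma = FALSE, lam = FALSE)
    boundary[free] <- pmin(u_best - lo[free], up[free] - u_best) < 1e-3
    starts_tab <- data.frame(starts[, , drop = FALSE],
                             objective = vals,
                             converged = vapply(runs, `[[`, TRUE, "converged"))
    names(starts_tab)[1:3] <- c("rho", "gamma", "lam")
  }

  structure(list(params = params, objective = val, converged = converged,
                 n_eval = counter$n, starts = starts_tab,
                 boundary = boundary, model = model,
                 theta_hat = estimate_theta(n_hap(x)),
                 n = n_hap(x), S = n_snp(x),
                 region_length = x$region_length,
                 theta_watterson = watterson_theta(x),
                 order = order, n_orders = n_orders, order_seed = order_seed,
                 control = control, call = match.call()),
            class = "recfit")
}

#' @export
coef.recfit <- function(object, ...) {
  p <- object$params
  # a gamma pinned at the lower search bound means no conversion signal
  if (object$model != "crossover" && object$boundary["gamma"] &&
      abs(log10(p["gamma"]) - object$control$lower[2]) < 1e-2) {
    p["gamma"] <- 0
    p["lam"] <- 0
  }
  p
}

#' @export
logLik.recfit <- function(object, ...) {
  structure(object$objective,
            df = switch(object$model, full = 3L, conversion = 2L, 1L),
            class = "logLik")
}

#' @export
print.recfit <- function(x, digits = 4, ...) {
  cat(sprintf("PAC copying model fit (%s), n=%d haplotypes, S=%d SNPs, %.4g kb\n",
              x$model, x$n, x$S, x$region_length))
  est <- coef(x)
  cat(sprintf("  rho    = %.*g /kb\n  gamma  = %.*g /kb\n  lambda = %.*g kb\n",
              digits, est["rho"], digits, est["gamma"], digits, est["lam"]))
  cat(sprintf("  objective %.6g, %d evaluations, converged: %s\n",
              x$objective, x$n_eval, x$converged))
  if (any(x$boundary))
    cat("  note: parameter(s) at search bound:",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.recfit <- function(object, ...) {
  out <- list(fit = object, coef = coef(object),
              theta_watterson = object$theta_watterson)
  class(out) <- "summary.recfit"
  out
}

#' @export
print.summary.recfit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Watterson theta of the data: %.4g /kb\n", x$theta_watterson))
  cat("  per-start objectives:\n")
  print(x$fit$starts, row.names = FALSE)
  invisible(x)
}

#' Simulate haplotype datasets from a fitted model
#'
#' Draws coalescent samples of the same size and region length as the data
#' the model was fitted to, using the fitted rates and the data's Watterson
#' mutation-rate estimate. This is the resampling engine of the parametric
#' bootstrap. A fitted gamma sitting at the lower search bound is treated
#' as 0 (no conversion in the replicates).
#'
#' @param object a \code{\link{recfit}} object.
#' @param nsim number of datasets.
#' @param seed integer seed; replicate streams are derived from it.
#' @param theta optional mutation rate per kb overriding the Watterson
#'   estimate.
#' @param ... unused.
#' @return a list of \code{\link{haplotypes}} objects.
#' @export
simulate.recfit <- function(object, nsim = 1, seed = NULL, theta = NULL, ...) {
  p <- coef(object)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(theta)) theta <- object$theta_watterson
  rep_seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  lapply(rep_seeds, function(s)
    sim_haplotypes(object$n, object$region_length, theta,
                   rho = p["rho"], gamma = p["gamma"], lam = p["lam"],
                   seed = s))
}
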