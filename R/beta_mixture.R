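# Beta-mixture bipolarity machinery: EM fits of 1- and 2-component
# mixtures to per-unit methylation levels and a likelihood-ratio test
# calibrated by parametric bootstrap.
#
# Two likelihood models share one interface. Continuous levels use beta
# densities on levels shrunk into (eps, 1 - eps). Read-derived levels
# (k methylated calls out of n_sites) are discrete, and evaluating a
# continuous density at those atoms misbehaves, so they use the
# binomial-integrated form: a beta-binomial mixture on the counts.
# In both models the single-component null is constrained to unimodal
# shapes (alpha, beta >= 1): a homogeneous cell population varies
# unimodally around its mean, whereas a U-shaped level distribution is
# itself a signature of bipolarity and belongs to the alternative.

#' Fit 1- and 2-component beta mixtures to unit methylation levels
#'
#' With `n_sites = 0` the model is a mixture of beta densities on levels
#' shrunk to the open interval `(eps, 1 - eps)` (with 4-site unit levels
#' the default `eps = 1/8` moves 0 and 1 half a site toward 0.5); the EM
#' uses k-means(2) initial partitions (`n_restarts` random starts). With
#' `n_sites > 0` levels are interpreted as counts out of `n_sites` calls
#' and the model is a beta-binomial mixture on the counts, fitted
#' deterministically from every split-threshold start. Both include a
#' start at the 1-component solution, so the fitted 2-component
#' log-likelihood is never below the 1-component one. The 1-component fit
#' is constrained to unimodal shapes (both `>= 1`). Components are
#' ordered so that component 1 is the hypomethylated one.
#'
#' @param levels numeric vector of per-unit methylation levels in `[0, 1]`.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param n_restarts number of k-means initial partitions (continuous
#'   model only).
#' @param eps boundary shrinkage (continuous model only).
#' @param n_sites calls per unit level; 0 selects the continuous model.
#' @param seed optional integer seed (continuous-model restart
#'   randomness only).
#' @return an object of class `beta_mixture_fit`: list with `weights`,
#'   `alpha`, `beta` (component shapes), `resp` (n x 2 responsibilities),
#'   `ll1`, `ll2`, `fit1` (constrained single-component shapes),
#'   `converged`, `degenerate`, `model` (`"beta"` or `"beta-binomial"`),
#'   `levels`, `counts`, `n`, `eps`, `n_sites`.
#' @export
fit_beta_mixture <- function(levels, max_iter = 200L, tol = 1e-6,
                             n_restarts = 5L, eps = 0.125, n_sites = 0L,
                             seed = NULL) {
  stopifnot(length(levels) >= 2L, all(levels >= 0), all(levels <= 1))
  model <- if (n_sites > 0L) "beta-binomial" else "beta"
  n <- length(levels)
  if (max(levels) - min(levels) < 1e-10) {
    fit <- list(weights = c(0.5, 0.5), alpha = c(NA_real_, NA_real_),
                beta = c(NA_real_, NA_real_),
                resp = matrix(0.5, n, 2), ll1 = 0, ll2 = 0,
                fit1 = c(NA_real_, NA_real_), converged = TRUE,
                degenerate = TRUE, model = model, levels = levels,
                counts = NULL, n = n, eps = eps, n_sites = n_sites)
    class(fit) <- "beta_mixture_fit"
    return(fit)
  }
  if (model == "beta-binomial") {
    k <- as.integer(round(levels * n_sites))
    stopifnot(all(abs(k - levels * n_sites) < 1e-6))
    fit <- cpp_fit_bb_mixture(k, as.integer(n_sites), as.integer(max_iter),
                              tol)
    fit$counts <- k
    fit$levels <- levels
  } else {
    x <- pmin(pmax(levels, eps), 1 - eps)
    fit <- with_seed(seed, cpp_fit_beta_mixture(x, as.integer(max_iter),
                                                tol, as.integer(n_restarts)))
    fit$counts <- NULL
    fit$levels <- x
  }
  fit$model <- model
  fit$n <- n
  fit$eps <- eps
  fit$n_sites <- as.integer(n_sites)
  class(fit) <- "beta_mixture_fit"
  fit
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat("beta mixture fit (", x$model, "): n = ", x$n, "\n", sep = "")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate (no bipolarity)\n")
  } else {
    mu <- x$alpha / (x$alpha + x$beta)
    cat(sprintf("  component means %.3f / %.3f, weights %.2f / %.2f\n",
                mu[1], mu[2], x$weights[1], x$weights[2]))
    cat(sprintf("  ll1 = %.3f, ll2 = %.3f, LRT = %.3f\n",
                x$ll1, x$ll2, 2 * (x$ll2 - x$ll1)))
  }
  invisible(x)
}

#' Hard unit partition from a mixture fit
#'
#' Units are assigned to the component with the larger responsibility;
#' component 1 is the hypomethylated subset.
#'
#' @param fit a `beta_mixture_fit`.
#' @return integer vector of 1 (hypo) / 2 (hyper) assignments.
#' @export
mixture_partition <- function(fit) {
  ifelse(fit$resp[, 2] > fit$resp[, 1], 2L, 1L)
}

#' Bipolarity test for a beta-mixture fit
#'
#' Tests whether two methylation states are required to explain the unit
#' levels, via the likelihood-ratio statistic of the 2- vs 1-component
#' mixture (the 1-component null constrained to unimodal shapes).
#' Mixture-order LRTs are non-regular, so the default null distribution
#' is a parametric bootstrap from the constrained 1-component fit; a fast
#' chi-square(2) approximation is available. For calibration, the
#' observed statistic is recomputed with the same (lighter) EM settings
#' used for the bootstrap replicates.
#'
#' @param fit a `beta_mixture_fit`; its `model` decides whether bootstrap
#'   replicates are continuous beta draws or beta-binomial counts.
#' @param method `"bootstrap"` (default) or `"chisq"`.
#' @param B bootstrap replicates.
#' @param seed optional integer seed.
#' @param boot_max_iter,boot_restarts EM settings used for both the
#'   bootstrap replicates and the re-evaluated observed statistic.
#' @return p-value in `[0, 1]`.
#' @export
test_bipolarity <- function(fit, method = c("bootstrap", "chisq"), B = 200L,
                            seed = NULL, boot_max_iter = 40L,
                            boot_restarts = 2L) {
  method <- match.arg(method)
  if (isTRUE(fit$degenerate) || !isTRUE(fit$converged)) return(1)
  if (method == "chisq") {
    lam <- max(0, 2 * (fit$ll2 - fit$ll1))
    return(pchisq(lam, df = 2, lower.tail = FALSE))
  }
  with_seed(seed, {
    if (fit$model == "beta-binomial") {
      lam_obs <- cpp_lrt_stat_bb(fit$counts, fit$n_sites,
                                 as.integer(boot_max_iter), 1e-5,
                                 as.integer(boot_restarts))
      lam_null <- cpp_lrt_bootstrap_bb(fit$n, fit$n_sites, fit$fit1[1],
                                       fit$fit1[2], as.integer(B),
                                       as.integer(boot_max_iter), 1e-5,
                                       as.integer(boot_restarts))
    } else {
      lam_obs <- cpp_lrt_stat(fit$levels, as.integer(boot_max_iter), 1e-5,
                              as.integer(boot_restarts))
      lam_null <- cpp_lrt_bootstrap(fit$n, fit$fit1[1], fit$fit1[2],
                                    as.integer(B), fit$eps, 0L,
                                    as.integer(boot_max_iter), 1e-5,
                                    as.integer(boot_restarts))
    }
    (1 + sum(lam_null >= lam_obs)) / (length(lam_null) + 1)
  })
}
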