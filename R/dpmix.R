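# Dirichlet-process mixture of product-Bernoulli components over 4-bit
# methylation patterns, by collapsed Gibbs sampling. Used in bulk mode to
# partition the reads of a candidate segment into methylation states.

#' Cluster read patterns with a Dirichlet-process mixture
#'
#' Collapsed Gibbs sampler for a DP mixture of product-Bernoulli
#' components with a Beta(1, 1) base measure per site and concentration
#' `alpha_dp`. The partition with the highest joint posterior visited
#' after burn-in is returned. Chains in which that partition was visited
#' in fewer than 5 percent of post-burn-in sweeps are flagged as possibly
#' non-mixing.
#'
#' @param patterns character vector of 4-bit patterns (one per read).
#' @param alpha_dp DP concentration.
#' @param sweeps total Gibbs sweeps.
#' @param burn_in sweeps discarded before tracking the best partition.
#' @param seed optional integer seed.
#' @return list with `assignment` (integer cluster labels, compacted),
#'   `n_clusters`, `log_posterior`, `mixing_ok`.
#' @export
cluster_patterns_bulk <- function(patterns, alpha_dp = 1.0, sweeps = 500L,
                                  burn_in = 100L, seed = NULL) {
  stopifnot(sweeps > burn_in)
  X <- do.call(rbind, lapply(strsplit(patterns, "", fixed = TRUE), as.integer))
  n <- nrow(X)
  S <- ncol(X)
  with_seed(seed, {
    z <- rep(1L, n)
    # cluster sufficient stats: counts and per-site methylated counts
    nc <- c(n)
    mc <- matrix(colSums(X), nrow = 1)
    log_joint <- function(nc, mc) {
      k <- length(nc)
      lp <- k * log(alpha_dp) + sum(lgamma(nc))
      for (cl in seq_len(k)) {
        lp <- lp + sum(lbeta(mc[cl, ] + 1, nc[cl] - mc[cl, ] + 1))
      }
      lp
    }
    best <- list(lp = -Inf, z = z)
    hits <- 0L
    visits <- 0L
    for (sw in seq_len(sweeps)) {
      for (i in seq_len(n)) {
        cl <- z[i]
        nc[cl] <- nc[cl] - 1L
        mc[cl, ] <- mc[cl, ] - X[i, ]
        if (nc[cl] == 0L) {
          nc <- nc[-cl]
          mc <- mc[-cl, , drop = FALSE]
          z[z > cl] <- z[z > cl] - 1L
        }
        k <- length(nc)
        # predictive log-probabilities: existing clusters then a new one
        lp <- numeric(k + 1L)
        for (c2 in seq_len(k)) {
          ps <- (mc[c2, ] + 1) / (nc[c2] + 2)
          lp[c2] <- log(nc[c2]) + sum(ifelse(X[i, ] == 1L, log(ps), log1p(-ps)))
        }
        lp[k + 1L] <- log(alpha_dp) + S * log(0.5)
        p <- exp(lp - max(lp))
        cl_new <- sample.int(k + 1L, 1L, prob = p)
        if (cl_new == k + 1L) {
          nc <- c(nc, 1L)
          mc <- rbind(mc, X[i, ])
        } else {
          nc[cl_new] <- nc[cl_new] + 1L
          mc[cl_new, ] <- mc[cl_new, ] + X[i, ]
        }
        z[i] <- cl_new
      }
      if (sw > burn_in) {
        visits <- visits + 1L
        lp_now <- log_joint(nc, mc)
        if (lp_now > best$lp + 1e-12) {
          best <- list(lp = lp_now, z = z)
          hits <- 1L
        } else if (abs(lp_now - best$lp) <= 1e-12) {
          hits <- hits + 1L
        }
      }
    }
    list(assignment = best$z,
         n_clusters = length(unique(best$z)),
         log_posterior = best$lp,
         mixing_ok = hits >= max(1L, floor(0.05 * visits)))
  })
}

# reduce a DP partition to hypo/hyper subsets: clusters are assigned by
# whether their mean read level falls below or above the midpoint of the
# cluster-mean range
dp_to_subsets <- function(assignment, levels) {
  cl_means <- tapply(levels, assignment, mean)
  if (length(cl_means) == 1L) {
    return(rep(1L, length(assignment)))
  }
  mid <- (min(cl_means) + max(cl_means)) / 2
  hyper_cl <- as.integer(names(cl_means)[cl_means > mid])
  ifelse(assignment %in% hyper_cl, 2L, 1L)
}
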