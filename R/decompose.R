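# decompose: constrained, regularized NMF of a loci-by-samples
# methylation matrix N ~ W H with W in [0,1]^(L x k) (latent methylation
# component profiles) and H columns on the probability simplex (mixing
# proportions). The regularizer lambda * sum W(1 - W) pushes profiles
# toward biologically plausible binary levels; it is minimized exactly at
# {0, 1}.

# exact simplex-constrained least squares per column:
#   min ||n - W h||^2  s.t.  h >= 0, sum(h) = 1
# active-set on the KKT system of the equality-constrained problem
simplex_ls <- function(W, n, ridge = 1e-12) {
  k <- ncol(W)
  if (k == 1L) return(1)
  A <- crossprod(W) + diag(ridge, k)
  b <- crossprod(W, n)
  active <- rep(TRUE, k)
  h <- rep(1 / k, k)
  for (iter in seq_len(10L * k)) {
    P <- which(active)
    kp <- length(P)
    # solve 2 A_PP h_P - nu = 2 b_P ; sum h_P = 1
    M <- rbind(cbind(2 * A[P, P, drop = FALSE], -1), c(rep(1, kp), 0))
    rhs <- c(2 * b[P], 1)
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      sol <- c(rep(1 / kp, kp), 0)   # singular face: fall back to uniform
    }
    hP <- sol[seq_len(kp)]
    nu <- sol[kp + 1L]
    if (any(hP < -1e-10)) {
      drop <- P[which.min(hP)]
      active[drop] <- FALSE
      if (sum(active) == 1L) {
        h <- as.numeric(seq_len(k) == which(active))
        P <- which(active)
        nu <- 2 * (A[P, P] - b[P])
        hP <- 1
      } else {
        next
      }
    }
    h <- numeric(k)
    h[which(active)] <- pmax(hP, 0)
    h <- h / sum(h)
    # KKT check on the zero set: multiplier 2(Ah - b)_i - nu must be >= 0
    g <- 2 * (A %*% h - b)
    viol <- which(!active & (g - nu < -1e-8))
    if (!length(viol)) return(h)
    active[viol[which.min(g[viol])]] <- TRUE
  }
  h
}

# H update: every column solved exactly on the simplex
update_H <- function(W, N) {
  H <- vapply(seq_len(ncol(N)), function(j) simplex_ls(W, N[, j]),
              numeric(ncol(W)))
  matrix(H, nrow = ncol(W))
}

# W update: exact coordinate descent over components, vectorized across
# loci. Per entry the objective in w is (||h_j||^2 - lambda) w^2 +
# (lambda - 2 c) w + const with c the residual inner product; when the
# quadratic coefficient is non-positive the minimum over [0,1] is at a
# boundary point.
update_W <- function(W, H, N, lambda, sweeps = 2L) {
  k <- nrow(H)
  R <- N - W %*% H                      # residual maintained incrementally
  for (s in seq_len(sweeps)) {
    for (j in seq_len(k)) {
      hj <- H[j, ]
      hh <- sum(hj^2)
      cj <- (R %*% hj) + W[, j] * hh    # c_i = (r_i + w_ij h_j) . h_j
      a <- hh - lambda
      if (a > 1e-12) {
        wnew <- pmin(pmax((2 * cj - lambda) / (2 * a), 0), 1)
      } else {
        # concave/linear per-coordinate objective: pick the better endpoint
        wnew <- as.numeric(a + lambda - 2 * cj < 0)
      }
      R <- R - outer(as.numeric(wnew - W[, j]), hj)
      W[, j] <- wnew
    }
  }
  W
}

nmf_objective <- function(N, W, H, lambda) {
  sum((N - W %*% H)^2) + lambda * sum(W * (1 - W))
}

#' Factorize a methylation matrix into latent methylation components
#'
#' Alternating minimization of
#' `||N - W H||_F^2 + lambda * sum_ij W_ij (1 - W_ij)`:
#' the H-step solves each sample column exactly on the probability simplex
#' (active-set QP), the W-step is exact coordinate descent over the box
#' `[0, 1]` with the binarizing penalty folded into the per-coordinate
#' quadratic. Both steps are exact block minimizations, so the objective
#' trace is non-increasing. The best of `n_restarts` randomized starts
#' (W initialized from observed sample columns plus jitter, H flat at
#' `1/k`) is returned.
#'
#' @param N numeric matrix, loci x samples, complete, entries in `[0, 1]`.
#' @param k number of latent components, `1 <= k <= min(dim(N))`.
#' @param lambda binarization penalty, `>= 0`.
#' @param n_restarts randomized restarts.
#' @param max_iter maximum alternating iterations per restart.
#' @param tol relative objective-decrease stopping tolerance.
#' @param seed integer seed.
#' @param track record per-iteration constraint diagnostics (maximum
#'   deviation of H column sums from 1, and the W range) in
#'   `$constraint_check`.
#' @return an `lmc_result`: list with `W`, `H`, `objective_trace` (of the
#'   best restart), `k`, `lambda`, `n_restarts`, `best_restart`,
#'   `converged`, and optionally `constraint_check`.
#' @export
factorize <- function(N, k, lambda = 0, n_restarts = 10L, max_iter = 200L,
                      tol = 1e-8, seed = NULL, track = FALSE) {
  stopifnot(is.matrix(N), !anyNA(N), k >= 1L)
  if (k > min(dim(N))) stop("k exceeds matrix dimensions")
  L <- nrow(N)
  S <- ncol(N)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cols <- sample.int(S, k, replace = k > S)
      W <- N[, cols, drop = FALSE] +
        matrix(runif(L * k, -0.05, 0.05), L, k)
      W <- pmin(pmax(W, 0), 1)
      H <- matrix(1 / k, k, S)
      trace <- nmf_objective(N, W, H, lambda)
      converged <- FALSE
      checks <- if (track) list() else NULL
      for (it in seq_len(max_iter)) {
        H <- update_H(W, N)
        W <- update_W(W, H, N, lambda)
        obj <- nmf_objective(N, W, H, lambda)
        trace <- c(trace, obj)
        if (track) {
          checks[[it]] <- c(h_simplex_dev = max(abs(colSums(H) - 1)),
                            w_min = min(W), w_max = max(W))
        }
        prev <- trace[length(trace) - 1L]
        if (prev - obj < tol * (abs(prev) + 1)) {
          converged <- TRUE
          break
        }
      }
      if (is.null(best) || obj < best$objective) {
        best <- list(W = W, H = H, objective = obj, objective_trace = trace,
                     best_restart = r, converged = converged,
                     constraint_check = if (track) do.call(rbind, checks))
      }
    }
    rownames(best$W) <- rownames(N)
    colnames(best$W) <- paste0("LMC", seq_len(k))
    rownames(best$H) <- colnames(best$W)
    colnames(best$H) <- colnames(N)
    out <- list(W = best$W, H = best$H,
                objective_trace = best$objective_trace,
                k = as.integer(k), lambda = lambda,
                n_restarts = as.integer(n_restarts),
                best_restart = best$best_restart,
                converged = best$converged,
                constraint_check = best$constraint_check)
    class(out) <- "lmc_result"
    out
  })
}

#' @export
print.lmc_result <- function(x, ...) {
  cat(sprintf("LMC factorization: %d loci x %d samples, k = %d, lambda = %g\n",
              nrow(x$W), ncol(x$H), x$k, x$lambda))
  cat(sprintf("  final objective %.6g after %d iterations (restart %d)\n",
              tail(x$objective_trace, 1), length(x$objective_trace) - 1L,
              x$best_restart))
  invisible(x)
}

# box-constrained least squares rows: min ||n - w H||^2, 0 <= w <= 1,
# exact coordinate descent (used to project held-out loci onto a fitted H)
box_ls_row <- function(H, n, max_sweeps = 200L, tol = 1e-12) {
  k <- nrow(H)
  w <- rep(0.5, k)
  r <- n - drop(w %*% H)
  hh <- rowSums(H^2)
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(k)) {
      if (hh[j] < 1e-14) next
      cj <- sum((r + w[j] * H[j, ]) * H[j, ])
      wnew <- min(max(cj / hh[j], 0), 1)
      if (wnew != w[j]) {
        r <- r - (wnew - w[j]) * H[j, ]
        delta <- max(delta, abs(wnew - w[j]))
        w[j] <- wnew
      }
    }
    if (delta < tol) break
  }
  w
}

#' Cross-validate the number of components and the penalty
#'
#' Loci are split into `folds` folds. For each `(k, lambda)` the model is
#' fitted on the training loci; each held-out locus row is then regressed
#' onto the fitted `H` under box constraints and the mean squared
#' reconstruction error of held-out entries is recorded. Both the global
#' minimizer and the smallest `(k, lambda)` within one standard error of
#' it (1-SE rule) are reported.
#'
#' @param N loci x samples matrix.
#' @param k_grid,lambda_grid candidate values.
#' @param folds number of locus folds, `>= 2`.
#' @param n_restarts restarts per fit (lighter than the final fit).
#' @param seed integer seed.
#' @return a `cv_grid`: list with `grid` (`data.table` of k, lambda, fold,
#'   error), `summary` (mean/se per cell), `selected` (min rule) and
#'   `selected_1se`.
#' @export
cross_validate <- function(N, k_grid, lambda_grid = 0, folds = 10L,
                           n_restarts = 3L, seed = NULL) {
  if (folds < 2L) stop("folds >= 2 required")
  L <- nrow(N)
  stopifnot(L >= folds)
  with_seed(seed, {
    fold_of <- sample(rep(seq_len(folds), length.out = L))
    rows <- list()
    for (kk in k_grid) {
      for (lam in lambda_grid) {
        for (f in seq_len(folds)) {
          train <- N[fold_of != f, , drop = FALSE]
          test <- N[fold_of == f, , drop = FALSE]
          fit <- factorize(train, k = kk, lambda = lam,
                           n_restarts = n_restarts, max_iter = 100L,
                           seed = sample.int(2^31 - 1, 1))
          wte <- vapply(seq_len(nrow(test)),
                        function(i) box_ls_row(fit$H, test[i, ]),
                        numeric(kk))
          Wte <- matrix(wte, ncol = kk, byrow = TRUE)
          err <- mean((test - Wte %*% fit$H)^2)
          rows[[length(rows) + 1L]] <- data.table(
            k = kk, lambda = lam, fold = f, error = err)
        }
      }
    }
    grid <- rbindlist(rows)
    summ <- grid[, list(mean_error = mean(error),
                        se = sd(error) / sqrt(.N)), by = c("k", "lambda")]
    setorder(summ, k, lambda)
    i_min <- which.min(summ$mean_error)
    thresh <- summ$mean_error[i_min] + summ$se[i_min]
    ok <- which(summ$mean_error <= thresh)
    i_1se <- ok[order(summ$k[ok], summ$lambda[ok])][1]
    out <- list(grid = grid, summary = summ,
                selected = list(k = summ$k[i_min], lambda = summ$lambda[i_min]),
                selected_1se = list(k = summ$k[i_1se],
                                    lambda = summ$lambda[i_1se]))
    class(out) <- "cv_grid"
    out
  })
}

#' @export
print.cv_grid <- function(x, ...) {
  cat("cross-validation over", nrow(x$summary), "grid cells\n")
  cat(sprintf("  min rule: k = %d, lambda = %g\n",
              x$selected$k, x$selected$lambda))
  cat(sprintf("  1-SE rule: k = %d, lambda = %g\n",
              x$selected_1se$k, x$selected_1se$lambda))
  invisible(x)
}

#' Match latent components to reference profiles
#'
#' Pearson correlation of every LMC column of `W` with every reference
#' column; mutual best matches are accepted, ties (equal best correlation)
#' make a column ambiguous and therefore unmatched. Constant columns have
#' undefined correlation and are unmatched with a warning.
#'
#' @param W loci x k profile matrix.
#' @param references loci x types reference matrix over the same loci
#'   (rows are aligned by name when both are named).
#' @param tie_tol correlations closer than this are considered tied.
#' @return an `lmc_assignment`: list with `pairs` (`data.table` of `lmc`,
#'   `reference`, `cor`), `unmatched_lmcs`, `unmatched_refs`.
#' @export
match_lmcs <- function(W, references, tie_tol = 1e-9) {
  if (!is.null(rownames(W)) && !is.null(rownames(references))) {
    common <- intersect(rownames(W), rownames(references))
    stopifnot(length(common) >= 2L)
    W <- W[common, , drop = FALSE]
    references <- references[common, , drop = FALSE]
  }
  stopifnot(nrow(W) == nrow(references))
  if (is.null(colnames(W))) colnames(W) <- paste0("LMC", seq_len(ncol(W)))
  if (is.null(colnames(references))) {
    colnames(references) <- paste0("ref", seq_len(ncol(references)))
  }
  const_w <- apply(W, 2, function(x) sd(x) < 1e-12)
  const_r <- apply(references, 2, function(x) sd(x) < 1e-12)
  if (any(const_w) || any(const_r)) {
    warning("constant column(s): correlation undefined, left unmatched")
  }
  cmat <- suppressWarnings(cor(W, references))
  cmat[is.na(cmat)] <- -Inf
  best_ref <- apply(cmat, 1, which.max)
  best_lmc <- apply(cmat, 2, which.max)
  pairs <- list()
  for (i in seq_len(ncol(W))) {
    j <- best_ref[i]
    if (!is.finite(cmat[i, j])) next
    # mutual best and untied in both directions
    if (best_lmc[j] != i) next
    if (sum(cmat[i, ] >= cmat[i, j] - tie_tol) > 1L) next
    if (sum(cmat[, j] >= cmat[i, j] - tie_tol) > 1L) next
    pairs[[length(pairs) + 1L]] <- data.table(
      lmc = colnames(W)[i], reference = colnames(references)[j],
      cor = cmat[i, j])
  }
  pairs <- if (length(pairs)) rbindlist(pairs)
           else data.table(lmc = character(), reference = character(),
                           cor = numeric())
  out <- list(pairs = pairs,
              unmatched_lmcs = setdiff(colnames(W), pairs$lmc),
              unmatched_refs = setdiff(colnames(references), pairs$reference))
  class(out) <- "lmc_assignment"
  out
}

#' @export
print.lmc_assignment <- function(x, ...) {
  cat("LMC assignment:", nrow(x$pairs), "matched pair(s)\n")
  if (nrow(x$pairs)) print(x$pairs)
  if (length(x$unmatched_refs)) {
    cat("unmatched references:", paste(x$unmatched_refs, collapse = ", "), "\n")
  }
  invisible(x)
}
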