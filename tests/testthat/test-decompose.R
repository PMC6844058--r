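random_meth_matrix <- function(L, S, seed) {
  set.seed(seed)
  m <- matrix(runif(L * S), L, S)
  rownames(m) <- paste0("L", seq_len(L))
  colnames(m) <- paste0("s", seq_len(S))
  m
}

planted_factorization <- function(L = 20, k = 3, S = 30, seed = 2) {
  set.seed(seed)
  W0 <- matrix(rbinom(L * k, 1, 0.5), L, k)
  # keep columns distinct and non-constant
  while (any(duplicated(t(W0))) || any(apply(W0, 2, sd) == 0)) {
    W0 <- matrix(rbinom(L * k, 1, 0.5), L, k)
  }
  H0 <- methylDissect:::rdirichlet_flat(k, S)
  N <- W0 %*% H0
  rownames(N) <- paste0("L", seq_len(L))
  colnames(N) <- paste0("s", seq_len(S))
  list(N = N, W0 = W0, H0 = H0)
}

test_that("k = 1, lambda = 0 reduces to row means exactly", {
  N <- random_meth_matrix(30, 6, seed = 1)
  f <- factorize(N, k = 1, lambda = 0, n_restarts = 2, seed = 3)
  expect_lt(max(abs(f$W[, 1] - rowMeans(N))), 1e-10)
  expect_equal(unname(f$H[1, ]), rep(1, 6))
})

test_that("the objective trace never increases", {
  for (s in 1:3) {
    N <- random_meth_matrix(25, 8, seed = s)
    for (lam in c(0, 1e-4, 1e-2)) {
      f <- factorize(N, k = 3, lambda = lam, n_restarts = 2, seed = s)
      expect_true(all(diff(f$objective_trace) <= 1e-9))
    }
  }
})

test_that("the simplex solver matches brute-force optimization", {
  set.seed(4)
  for (rep in 1:20) {
    W <- matrix(runif(12 * 2), 12, 2)
    n <- runif(12)
    h <- methylDissect:::simplex_ls(W, n)
    expect_equal(sum(h), 1, tolerance = 1e-10)
    expect_true(all(h >= -1e-12))
    # 1-D oracle over the segment h = (t, 1 - t)
    obj <- function(t) sum((n - W %*% c(t, 1 - t))^2)
    t_star <- optimize(obj, c(0, 1), tol = 1e-12)$minimum
    expect_equal(obj(h[1]), obj(t_star), tolerance = 1e-8)
  }
  # k = 3 against a fine simplex grid
  set.seed(5)
  W <- matrix(runif(30), 10, 3)
  n <- runif(10)
  h <- methylDissect:::simplex_ls(W, n)
  grid <- expand.grid(a = seq(0, 1, 0.02), b = seq(0, 1, 0.02))
  grid <- grid[grid$a + grid$b <= 1, ]
  vals <- apply(grid, 1, function(g) sum((n - W %*% c(g[1], g[2], 1 - g[1] - g[2]))^2))
  expect_lte(sum((n - W %*% h)^2), min(vals) + 1e-6)
})

test_that("planted binary factorizations are recovered up to permutation", {
  pf <- planted_factorization()
  f <- factorize(pf$N, k = 3, lambda = 1e-4, n_restarts = 10, seed = 5,
                 track = TRUE)
  cc <- abs(cor(f$W, pf$W0))
  perm <- apply(cc, 1, which.max)
  expect_setequal(perm, 1:3)
  expect_true(all(apply(cc, 1, max) > 0.99))
  # feasibility at every iterate
  expect_true(all(f$constraint_check[, "h_simplex_dev"] < 1e-8))
  expect_gte(min(f$constraint_check[, "w_min"]), 0)
  expect_lte(max(f$constraint_check[, "w_max"]), 1)
})

test_that("the binarization penalty drives W toward {0, 1} monotonically", {
  pf <- planted_factorization(seed = 6)
  N <- pf$N + matrix(rnorm(length(pf$N), 0, 0.02), nrow(pf$N))
  N <- pmin(pmax(N, 0), 1)
  softness <- vapply(c(0, 1e-3, 1e-1, 1), function(lam) {
    f <- factorize(N, k = 3, lambda = lam, n_restarts = 4, seed = 9)
    mean(f$W * (1 - f$W))
  }, 0)
  expect_true(all(diff(softness) <= 1e-6))
})

test_that("duplicating a sample column duplicates its proportions", {
  pf <- planted_factorization(seed = 7)
  f <- factorize(pf$N, k = 3, lambda = 0, n_restarts = 5, seed = 2)
  # deterministic solver property: identical columns get identical h
  N2 <- cbind(pf$N, dup = pf$N[, 1])
  H2 <- methylDissect:::update_H(f$W, N2)
  expect_equal(H2[, 1], H2[, ncol(N2)])
  # and a full refit still recovers the same subspace
  f2 <- factorize(N2, k = 3, lambda = 0, n_restarts = 5, seed = 2)
  cc <- abs(cor(f2$W, f$W))
  expect_true(all(apply(cc, 1, max) > 0.98))
})

test_that("cross-validation reduces to the row-mean model for k = 1", {
  N <- random_meth_matrix(20, 6, seed = 8)
  cv <- cross_validate(N, k_grid = 1, lambda_grid = 0, folds = 5,
                       n_restarts = 1, seed = 3)
  # each locus appears in exactly one test fold, with equal fold sizes the
  # pooled CV error is the mean clipped-row-mean residual
  want <- mean(vapply(seq_len(nrow(N)), function(i) {
    mean((N[i, ] - min(max(mean(N[i, ]), 0), 1))^2)
  }, 0))
  expect_equal(cv$summary$mean_error, want, tolerance = 1e-10)
  expect_error(cross_validate(N, 1, 0, folds = 1), "folds")
})

test_that("component matching is mutual-best with tie protection", {
  set.seed(9)
  refs <- matrix(runif(60), 20, 3,
                 dimnames = list(paste0("L", 1:20), paste0("t", 1:3)))
  # identity self-match
  m <- match_lmcs(refs, refs)
  expect_equal(nrow(m$pairs), 3L)
  expect_equal(m$pairs$reference[match(paste0("t", 1:3), m$pairs$lmc)],
               paste0("t", 1:3))
  # a duplicated reference ties and stays unmatched
  refs2 <- cbind(refs, t4 = refs[, 1])
  m2 <- match_lmcs(refs[, 1, drop = FALSE], refs2)
  expect_false("t1" %in% m2$pairs$reference)
  expect_false("t4" %in% m2$pairs$reference)
  # constant columns warn and stay unmatched
  refs3 <- refs
  refs3[, 2] <- 0.5
  expect_warning(m3 <- match_lmcs(refs, refs3), "constant")
  expect_false("t2" %in% m3$pairs$reference)
})
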