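# independent 2-component beta-mixture EM (optim-based M-step), used as a
# cross-check of the compiled fit
r_em_beta2 <- function(x, starts = 5, iters = 60) {
  dmix <- function(x, th) {
    th$w * dbeta(x, th$a1, th$b1) + (1 - th$w) * dbeta(x, th$a2, th$b2)
  }
  fit_w <- function(x, w) {
    # same concentration cap as the package fit, so likelihoods at
    # clamped atoms stay comparable
    nll <- function(p) -sum(w * dbeta(x, exp(p[1]), exp(p[2]), log = TRUE))
    p <- exp(optim(c(0, 0), nll)$par)
    if (sum(p) > 1e3) p <- p * 1e3 / sum(p)
    p
  }
  best <- list(ll = -Inf)
  set.seed(99)
  for (s in seq_len(starts)) {
    cut <- runif(1, min(x), max(x))
    r1 <- ifelse(x <= cut, 0.9, 0.1)
    th <- list(w = 0.5, a1 = 1, b1 = 1, a2 = 1, b2 = 1)
    for (i in seq_len(iters)) {
      th$w <- mean(r1)
      p1 <- fit_w(x, r1); p2 <- fit_w(x, 1 - r1)
      th$a1 <- p1[1]; th$b1 <- p1[2]; th$a2 <- p2[1]; th$b2 <- p2[2]
      d1 <- th$w * dbeta(x, th$a1, th$b1)
      r1 <- d1 / (d1 + (1 - th$w) * dbeta(x, th$a2, th$b2))
    }
    ll <- sum(log(dmix(x, th)))
    if (is.finite(ll) && ll > best$ll) best <- list(ll = ll, th = th)
  }
  best
}

test_that("candidate gate requires both complete patterns", {
  expect_true(is_candidate(c(rep("1010", 8), "1111", "0000")))
  expect_false(is_candidate(c(rep("1110", 5), rep("0000", 5))))
  expect_false(is_candidate(rep("1111", 10)))
})

test_that("unit levels are methylated-site fractions", {
  expect_equal(unit_levels("1101"), 0.75)
  expect_equal(unit_levels("0000"), 0)
  expect_length(unit_levels(c("1111", "0101", "0001")), 3L)
})

test_that("separated populations are split with a large level difference", {
  set.seed(1)
  x <- c(rbeta(10, 20, 1), rbeta(10, 1, 20))
  f <- fit_beta_mixture(x, seed = 42)
  mu <- f$alpha / (f$alpha + f$beta)
  expect_lt(mu[1], 0.5)
  expect_gt(mu[2], 0.5)
  part <- mixture_partition(f)
  sub_mu <- tapply(x, part, mean)
  expect_gt(sub_mu[["2"]] - sub_mu[["1"]], 0.8)
  expect_gte(f$ll2, f$ll1)
  # cross-check against an independent EM implementation
  ref <- r_em_beta2(f$levels)
  expect_gte(f$ll2, ref$ll - 0.1)
})

test_that("mixture fit is mirror-symmetric", {
  set.seed(1)
  x <- c(rbeta(10, 20, 1), rbeta(10, 1, 20))
  f <- fit_beta_mixture(x, seed = 42)
  fm <- fit_beta_mixture(1 - x, seed = 42)
  mu <- f$alpha / (f$alpha + f$beta)
  mum <- fm$alpha / (fm$alpha + fm$beta)
  expect_equal(sort(mum), sort(1 - mu), tolerance = 0.05)
})

test_that("degenerate level sets are never significant", {
  f <- fit_beta_mixture(rep(0.5, 12))
  expect_true(f$degenerate)
  expect_equal(test_bipolarity(f), 1)
  expect_equal(test_bipolarity(f, method = "chisq"), 1)
})

test_that("a zero likelihood-ratio statistic maps to p = 1", {
  # constant data makes ll2 == ll1 by construction
  f <- fit_beta_mixture(rep(0.25, 15), n_sites = 4)
  expect_equal(2 * (f$ll2 - f$ll1), 0)
  expect_equal(test_bipolarity(f, method = "chisq"), 1)
})

test_that("well-separated data is extreme under the chisq approximation", {
  set.seed(1)
  x <- c(rbeta(10, 20, 1), rbeta(10, 1, 20))
  f <- fit_beta_mixture(x, seed = 42)
  expect_lt(test_bipolarity(f, method = "chisq"), 1e-6)
})

test_that("beta-binomial and beta models agree on clear bipolarity", {
  set.seed(5)
  u <- c(rbeta(15, 20, 1), rbeta(15, 1, 20))
  lv <- rbinom(30, 4, u) / 4
  fb <- fit_beta_mixture(lv, n_sites = 4)
  expect_gte(fb$ll2, fb$ll1)
  expect_lt(test_bipolarity(fb, B = 200, seed = 3), 0.01)
  mu <- fb$alpha / (fb$alpha + fb$beta)
  expect_lt(mu[1], 0.35)
  expect_gt(mu[2], 0.65)
})

test_that("pCSM calls respect thresholds, gating and BH adjustment", {
  set.seed(21)
  planted <- make_planted_segments(12, 30, coverage = 30, seed = 7)
  calls <- call_pcsm(planted$profiles, seed = 5)
  expect_equal(nrow(calls), 42L)
  # gating: only candidates can have p_raw < 1
  cand <- vapply(split(planted$profiles$pattern,
                       planted$profiles$p1),
                 is_candidate, TRUE)
  calls_by_p1 <- calls[match(as.integer(names(cand)), calls$p1), ]
  expect_true(all(calls_by_p1$p_raw[!cand] == 1))
  expect_true(all(calls_by_p1$p_adj[!cand] == 1))
  # BH monotonicity and effect floor
  expect_true(all(calls$p_adj >= calls$p_raw - 1e-12))
  expect_true(all(calls$diff[calls$is_pcsm] > 0.30))
  expect_true(all(calls$p_adj[calls$is_pcsm] < 0.05))
  expect_true(all(calls$mu_hypo <= calls$mu_hyper, na.rm = TRUE))
  # reordering input does not change adjusted p-values
  shuf <- planted$profiles[sample(nrow(planted$profiles)), ]
  data.table::setattr(shuf, "mode", "single_cell")
  data.table::setattr(shuf, "class", c("segment_profiles", class(shuf)))
  calls2 <- call_pcsm(shuf, seed = 5)
  data.table::setkey(calls, chrom, p1)
  expect_equal(calls2[order(chrom, p1)]$p_adj, calls[order(chrom, p1)]$p_adj)
})

test_that("an effect-size floor excludes small differences regardless of p", {
  # candidate whose subsets differ by < 0.30: two tight populations at
  # 0.35 and 0.55 plus one complete pattern each to pass the gate
  set.seed(8)
  pats <- c(patterns_at_levels(rep(0.4, 20)), "1111", "0000")
  profs <- profiles_from_patterns(list(pats))
  calls <- call_pcsm(profs, seed = 2)
  if (!is.na(calls$diff) && calls$diff <= 0.30) {
    expect_false(calls$is_pcsm)
  }
  # the calling rule as an implication: pCSM => both thresholds met
  expect_true(all(!calls$is_pcsm |
                    (calls$diff > 0.30 & calls$p_adj < 0.05)))
})

test_that("subset difference statistics match direct recomputation", {
  profs <- profiles_from_patterns(list(
    rep("1111", 10),
    c(rep("1111", 5), rep("0000", 5)),
    c(rep("1100", 6), rep("0011", 6))))
  st <- subset_diff_stats(profs, seed = 3)
  st <- st[order(st$p1), ]
  expect_equal(st$mean_level, c(1, 0.5, 0.5))
  expect_equal(st$diff[1], 0)      # single subset: zero by convention
  expect_equal(st$diff[2], 1)
  # brute-force mean levels on random profiles
  set.seed(4)
  rnd <- profiles_from_patterns(lapply(1:8, function(i)
    patterns_at_levels(rbeta(15, 2, 2))))
  st2 <- subset_diff_stats(rnd, seed = 3)
  mean_brute <- vapply(split(rnd$pattern, rnd$p1), function(p) {
    mean(vapply(strsplit(p, ""), function(s) mean(s == "1"), 0))
  }, 0)
  expect_equal(st2[order(st2$p1)]$mean_level, unname(mean_brute))
  expect_true(all(st2$diff >= 0 & st2$diff <= 1))
})

test_that("DP clustering separates pure pattern mixtures in bulk mode", {
  pats <- c(rep("1111", 5), rep("0000", 5))
  res <- cluster_patterns_bulk(pats, seed = 1)
  expect_equal(res$n_clusters, 2L)
  part <- methylDissect:::dp_to_subsets(res$assignment, unit_levels(pats))
  expect_equal(length(unique(part)), 2L)
  mu <- tapply(unit_levels(pats), part, mean)
  expect_equal(unname(mu[["2"]] - mu[["1"]]), 1)
})

test_that("bulk-mode planted mixtures are called bipolar across seeds", {
  set.seed(2)
  pats <- c(rep("1111", 12), rep("0000", 8))
  ok <- vapply(1:10, function(s) {
    profs <- profiles_from_patterns(list(sample(pats)), mode = "bulk")
    calls <- call_pcsm(profs, mode = "bulk", seed = s)
    isTRUE(calls$is_pcsm)
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})
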