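# planted-block methylation matrix: n_blocks base profiles, each with
# `per_block` noisy copies
planted_blocks <- function(n_blocks, per_block, n_samples, noise = 0.05,
                           seed = 1, anticorrelated = FALSE) {
  set.seed(seed)
  bases <- lapply(seq_len(n_blocks), function(b) runif(n_samples))
  if (anticorrelated && n_blocks == 2L) bases[[2]] <- 1 - bases[[1]]
  m <- do.call(rbind, lapply(bases, function(b) {
    t(sapply(seq_len(per_block), function(i) b + rnorm(n_samples, 0, noise)))
  }))
  m <- pmin(pmax(m, 0), 1)
  rownames(m) <- paste0("L", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(n_samples))
  m
}

test_that("matrix construction pools calls, filters and imputes", {
  loci <- data.table::data.table(chrom = "chr1",
                                 start = c(100L, 500L), end = c(200L, 600L))
  sc <- data.table::data.table(
    sample_id = c("s1", "s1", "s2", "s2", "s1"),
    chrom = "chr1",
    pos = c(120L, 150L, 120L, 150L, 520L),
    meth = c(3L, 1L, 0L, 0L, 5L),
    total = c(4L, 4L, 4L, 2L, 5L))
  m <- build_matrix(loci, sc, min_samples_covered = 1L)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["chr1:100-200", "s1"], 4 / 8)
  expect_equal(m["chr1:100-200", "s2"], 0)
  # locus 2 covered only in s1: s2 imputed with the locus mean, flagged
  expect_equal(m["chr1:500-600", "s2"], 1)
  expect_true(attr(m, "imputed")["chr1:500-600", "s2"])
  # coverage filter drops locus 2 entirely
  m2 <- build_matrix(loci, sc, min_samples_covered = 2L)
  expect_equal(rownames(m2), "chr1:100-200")
  expect_error(build_matrix(loci, sc, min_samples_covered = 3L), "no locus")
})

test_that("k-means grouping orders groups by mean methylation", {
  set.seed(2)
  m <- rbind(matrix(runif(200, 0.0, 0.1), 10),
             matrix(runif(200, 0.45, 0.55), 10),
             matrix(runif(200, 0.9, 1.0), 10))
  rownames(m) <- paste0("L", 1:30)
  g <- kmeans_partition(m, k = 3, seed = 4)
  expect_named(g, c("hypo", "mid", "hyper"))
  expect_equal(lengths(g), c(hypo = 10L, mid = 10L, hyper = 10L))
  expect_true(all(g$hypo %in% 1:10))
  expect_true(all(g$hyper %in% 21:30))
  expect_equal(kmeans_partition(m, k = 1)$all, 1:30)
  # duplicated rows stay together
  m2 <- m[c(1, 1, 11, 11, 21, 21), ]
  g2 <- kmeans_partition(m2, k = 3, seed = 4)
  expect_true(all(vapply(g2, function(ix) length(unique((ix - 1) %/% 2)) == 1,
                         TRUE)))
})

test_that("soft threshold matches an independent scale-free computation", {
  m <- planted_blocks(4, 15, 12, noise = 0.15, seed = 3)
  st <- pick_soft_threshold(m, powers = 1:8)
  # independent recomputation of the fit index per power
  cmat <- cor(t(m))
  for (p in c(2L, 5L)) {
    a <- ((1 + cmat) / 2)^p
    diag(a) <- 0
    kk <- rowSums(a)
    brk <- unique(quantile(kk, seq(0, 1, length.out = 11)))
    bin <- cut(kk, brk, include.lowest = TRUE)
    dk <- tapply(kk, bin, mean)
    pk <- tapply(kk, bin, length) / length(kk)
    ok <- !is.na(dk) & pk > 0
    r <- suppressWarnings(cor(log10(pk[ok]), log10(dk[ok])))
    want <- if (!is.finite(r) || r > 0) 0 else r^2
    expect_equal(st$fit$r_squared[st$fit$power == p], want, tolerance = 1e-12)
  }
  # degenerate targets and inputs
  expect_equal(pick_soft_threshold(m, powers = 1:8, r2_target = 0)$power, 1L)
  mconst <- m
  mconst[1, ] <- 0.5
  expect_error(pick_soft_threshold(mconst), "zero variance")
})

test_that("signed modules separate anticorrelated blocks", {
  m <- planted_blocks(2, 15, 20, noise = 0.03, seed = 5,
                      anticorrelated = TRUE)
  mods <- detect_modules(m, soft_power = 6, min_module_size = 10)
  expect_length(mods$modules, 2L)
  # no mixed membership: each module is exactly one planted block
  blocks <- list(paste0("L", 1:15), paste0("L", 16:30))
  for (mem in mods$modules) {
    expect_true(setequal(mem, blocks[[1]]) || setequal(mem, blocks[[2]]))
  }
  # partition property
  assigned <- c(unlist(mods$modules), mods$unassigned)
  expect_setequal(assigned, rownames(m))
  expect_equal(anyDuplicated(assigned), 0L)
  # one coherent block collapses to a single module
  m1 <- planted_blocks(1, 20, 20, noise = 0.03, seed = 6)
  mods1 <- detect_modules(m1, soft_power = 6, min_module_size = 10)
  expect_length(mods1$modules, 1L)
  expect_setequal(mods1$modules$M1, rownames(m1))
})

test_that("eigen-locus selection ranks by PC1 loading with fixed sign", {
  set.seed(7)
  n_s <- 15
  base <- runif(n_s)                      # strong module profile
  noise_rows <- t(sapply(1:19, function(i) {
    pmin(pmax(0.5 + rnorm(n_s, 0, 0.04), 0), 1)
  }))
  m <- rbind(matrix(base, 1), noise_rows) # one profile locus, rest noise
  rownames(m) <- paste0("L", 1:20)
  colnames(m) <- paste0("s", 1:n_s)
  eig <- select_eigen_loci(rownames(m), m, fraction = 0.05)
  expect_equal(as.character(eig), "L1")   # the profile locus wins
  expect_gt(attr(eig, "pc1_var"), 0)
  # size formula and the all-members limit
  expect_length(select_eigen_loci(rownames(m), m, fraction = 1), 20L)
  m100 <- planted_blocks(1, 100, 12, seed = 8)
  expect_length(select_eigen_loci(rownames(m100), m100, fraction = 0.10), 10L)
  # sub-threshold modules return every member, flagged
  small <- select_eigen_loci(rownames(m)[1:5], m, fraction = 0.10)
  expect_length(small, 5L)
  expect_true(attr(small, "flagged"))
})

test_that("the co-methylation stage is deterministic under a fixed seed", {
  m <- planted_blocks(3, 20, 15, noise = 0.08, seed = 9)
  r1 <- run_comethylation(m, k = 3, fraction = 0.2, min_module_size = 8,
                          seed = 11)
  r2 <- run_comethylation(m, k = 3, fraction = 0.2, min_module_size = 8,
                          seed = 11)
  expect_identical(r1$eigen_loci, r2$eigen_loci)
  expect_identical(r1$assignment, r2$assignment)
})
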