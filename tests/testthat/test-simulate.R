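test_that("reference merging pools calls per type", {
  counts <- data.table::data.table(
    unit_id = c("c1", "c2", "c3"),
    locus = "chr1:100-177",
    meth = c(4L, 0L, 2L),
    total = c(4L, 4L, 4L))
  types <- data.table::data.table(cell_id = c("c1", "c2", "c3"),
                                  type = c("A", "A", "B"))
  refs <- merge_reference(counts, types)
  expect_equal(refs$levels["chr1:100-177", "A"], 0.5)   # (4+0)/(4+4)
  expect_equal(refs$levels["chr1:100-177", "B"], 0.5)
  expect_equal(refs$coverage["chr1:100-177", "A"], 8)
  # a single-cell "type" equals that cell
  one <- merge_reference(counts[1], types[1])
  expect_equal(one$levels[1, "A"], 1)
  expect_error(merge_reference(counts[1], types), "zero covered cells")
})

test_that("reference merging equals a brute-force pooling oracle", {
  set.seed(3)
  counts <- data.table::data.table(
    unit_id = sample(sprintf("c%02d", 1:12), 80, replace = TRUE),
    locus = sample(sprintf("chr1:%d-%d", (1:6) * 100, (1:6) * 100 + 77),
                   80, replace = TRUE),
    meth = sample(0:4, 80, replace = TRUE))
  counts$total <- counts$meth + sample(0:4, 80, replace = TRUE)
  counts <- counts[counts$total > 0, ]
  types <- data.table::data.table(cell_id = sprintf("c%02d", 1:12),
                                  type = rep(c("A", "B", "C"), each = 4))
  refs <- merge_reference(counts, types)
  mg <- merge(as.data.frame(counts), as.data.frame(types),
              by.x = "unit_id", by.y = "cell_id")
  for (lc in rownames(refs$levels)) {
    for (ty in colnames(refs$levels)) {
      sub <- mg[mg$locus == lc & mg$type == ty, ]
      want <- if (nrow(sub)) sum(sub$meth) / sum(sub$total) else NA_real_
      expect_equal(refs$levels[lc, ty], want)
    }
  }
})

test_that("mixture synthesis honors degenerate and equal-coverage cases", {
  refs <- matrix(runif(40), 10, 4,
                 dimnames = list(paste0("L", 1:10), paste0("t", 1:4)))
  P <- matrix(c(1, 0, 0, 0), 4, 1)
  mix <- synthesize_mixtures(refs, proportions = P, seed = 1)
  expect_equal(unname(mix$matrix[, 1]), unname(refs[, 1]))
  # equal coverage: plain convex combination
  P2 <- methylDissect:::rdirichlet_flat(4, 5)
  mix2 <- synthesize_mixtures(refs, proportions = P2, seed = 2)
  expect_equal(unname(mix2$matrix), unname(refs %*% P2))
  # convexity bounds
  expect_true(all(mix2$matrix >= apply(refs, 1, min) - 1e-12))
  expect_true(all(mix2$matrix <= apply(refs, 1, max) + 1e-12))
  # coverage-weighted mixing differs from plain mixing when unequal
  cov <- matrix(rexp(40) * 10 + 1, 10, 4)
  mix3 <- synthesize_mixtures(refs, coverage = cov, proportions = P2, seed = 3)
  expect_false(isTRUE(all.equal(mix3$matrix, refs %*% P2,
                                check.attributes = FALSE)))
  # truth table is reproducible bit-identically under a fixed seed
  a <- synthesize_mixtures(refs, n_samples = 100, seed = 7)
  b <- synthesize_mixtures(refs, n_samples = 100, seed = 7)
  expect_identical(a$truth, b$truth)
  expect_identical(a$matrix, b$matrix)
  expect_true(all(abs(colSums(a$proportions) - 1) < 1e-12))
})

test_that("the synthetic cell generator is seed-deterministic", {
  a <- generate_synthetic_cells(n_types = 3, cells_per_type = 10,
                                n_loci = 100, cover_rate = 0.3, seed = 5)
  b <- generate_synthetic_cells(n_types = 3, cells_per_type = 10,
                                n_loci = 100, cover_rate = 0.3, seed = 5)
  expect_identical(as.data.frame(a$reads), as.data.frame(b$reads))
  expect_identical(a$truth$levels, b$truth$levels)
  # planted separation honors the floor
  lv <- a$truth$levels[a$truth$loci$is_csm, , drop = FALSE]
  hy <- a$truth$loci$hyper_types[a$truth$loci$is_csm]
  seps <- vapply(seq_len(nrow(lv)), function(i) {
    min(lv[i, hy[[i]]]) - max(lv[i, setdiff(colnames(lv), hy[[i]])])
  }, 0)
  expect_true(all(seps > 0.3))
})

test_that("deep coverage recovers planted levels", {
  sim <- generate_synthetic_cells(n_types = 2, cells_per_type = 15,
                                  n_loci = 40, frac_csm = 0.5, depth = 200,
                                  cover_rate = 1, seed = 6)
  counts <- locus_level_counts(sim$reads, sim$truth$loci)
  refs <- merge_reference(counts, sim$truth$cells)
  truth_lv <- sim$truth$levels
  rownames(truth_lv) <- sim$truth$loci$locus
  common <- intersect(rownames(refs$levels), rownames(truth_lv))
  err <- abs(refs$levels[common, ] - truth_lv[common, colnames(refs$levels)])
  expect_lt(max(err), 0.05)
})

test_that("a null generator produces only FDR-level pCSM calls", {
  sim <- generate_synthetic_cells(n_types = 3, cells_per_type = 40,
                                  n_loci = 300, frac_csm = 0, seed = 8)
  segs <- extract_segments(sim$reads, "single_cell")
  segs <- filter_segments(segs, min_cov = 10)
  calls <- call_pcsm(segs, seed = 9)
  expect_gt(nrow(calls), 100)
  expect_lte(mean(calls$is_pcsm), 0.02)
})

test_that("hVar-CpG selection ranks by variance with stable ties", {
  set.seed(10)
  m <- matrix(runif(60), 6, 10)
  m[3, ] <- 0.4                      # constant: never selected early
  rownames(m) <- paste0("cg", 1:6)
  top <- select_hvar_cpgs(m, 5)
  expect_false("cg3" %in% top)
  expect_warning(all6 <- select_hvar_cpgs(m, 10), "exceeds")
  expect_setequal(all6, rownames(m))
  # oracle: explicit variance ranking
  v <- apply(m, 1, var)
  expect_equal(top, rownames(m)[order(-v)][1:5])
})

test_that("rmse and mae follow their defining formulas", {
  expect_equal(rmse(c(1, 0.4), c(1, 0.4)), 0)
  expect_equal(rmse(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(rmse(1:3 / 3, 1:2 / 2), "length mismatch")
  p16 <- setNames(c(0.16, rep(0.056, 15)), paste0("t", 1:16))
  est <- p16
  est["t1"] <- 0   # one unmatched type set to zero
  expect_equal(mae(p16, est[-1], n_types = 16), 0.01)
  expect_equal(mae(p16, p16), 0)
})

test_that("evaluation formulas agree with brute force on 1000 instances", {
  set.seed(12)
  for (i in 1:1000) {
    n <- sample(2:20, 1)
    m <- runif(n)
    mh <- runif(n)
    expect_equal(rmse(m, mh), rmse_brute(m, mh), tolerance = 1e-12)
    nt <- sample(2:16, 1)
    p <- setNames(as.vector(methylDissect:::rdirichlet_flat(nt, 1)),
                  paste0("t", 1:nt))
    keep <- sample(nt, sample.int(nt, 1))
    ph <- setNames(runif(length(keep)), paste0("t", keep))
    expect_equal(mae(p, ph, nt), mae_brute(as.list(p), as.list(ph), nt))
  }
})

test_that("truth tables round-trip through the TSV writer", {
  refs <- matrix(runif(20), 5, 4,
                 dimnames = list(paste0("L", 1:5), paste0("t", 1:4)))
  mix <- synthesize_mixtures(refs, n_samples = 6, seed = 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(mix$truth, tf)
  back <- read_truth_table(tf)
  expect_equal(back$sample_id, mix$truth$sample_id)
  expect_equal(back$proportion, mix$truth$proportion, tolerance = 1e-12)
})
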