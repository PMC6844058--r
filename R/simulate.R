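# simulate: synthetic single-cell datasets with planted cell-type-specific
# methylation, reference merging, mixture synthesis with known proportions,
# hVar-CpG baselines, and recovery scoring (RMSE, MAE, matched components).

#' Generate a synthetic single-cell read-pattern dataset
#'
#' Emulates a sparse single-cell bisulfite experiment over a synthetic
#' genome of non-overlapping 4-CpG loci. Each locus is either planted as
#' cell-type-specific (a random split of the types into hypermethylated,
#' levels drawn from `Beta(hyper_shape)`, and hypomethylated,
#' `Beta(hypo_shape)`, redrawn until the smallest hyper level exceeds the
#' largest hypo level by more than `min_planted_diff`) or shared
#' (one `Beta(noncsm_shape)` level for all types, mostly near 0 or 1 as in
#' real methylomes). Each cell covers each locus independently with
#' probability `cover_rate` (single-cell methylomes are shallow) and a
#' covered cell emits `depth` reads of four Bernoulli(level) site calls.
#'
#' @param n_types number of cell types.
#' @param cells_per_type cells per type.
#' @param n_loci number of 4-CpG loci.
#' @param frac_csm fraction of loci planted as cell-type-specific, in
#'   `(0, 1)` (0 allowed for null datasets).
#' @param depth reads per covered cell and locus.
#' @param cover_rate per-cell, per-locus coverage probability.
#' @param hyper_shape,hypo_shape,noncsm_shape beta shape pairs.
#' @param min_planted_diff guaranteed hyper-hypo separation of planted loci.
#' @param seed integer seed.
#' @return list with `reads` (a `read_calls` object), `truth` (list:
#'   `loci` table with coordinates, `is_csm`, per-type level matrix
#'   `levels`; `cells` table with `cell_id`, `type`).
#' @export
generate_synthetic_cells <- function(n_types = 5L, cells_per_type = 40L,
                                     n_loci = 5000L, frac_csm = 0.2,
                                     depth = 1L, cover_rate = 0.1,
                                     hyper_shape = c(12, 2),
                                     hypo_shape = c(2, 12),
                                     noncsm_shape = c(0.6, 0.6),
                                     min_planted_diff = 0.3,
                                     seed = NULL) {
  stopifnot(frac_csm >= 0, frac_csm < 1, n_types >= 2L, depth >= 1L)
  with_seed(seed, {
    n_chrom <- 5L
    chrom <- paste0("chr", ((seq_len(n_loci) - 1L) %% n_chrom) + 1L)
    idx_on_chr <- stats::ave(seq_len(n_loci), chrom, FUN = seq_along)
    p1 <- 1000L + (idx_on_chr - 1L) * 1000L
    pos <- cbind(p1, p1 + 25L, p1 + 50L, p1 + 75L)
    types <- paste0("type", seq_len(n_types))
    cells <- data.table(
      cell_id = sprintf("cell%03d", seq_len(n_types * cells_per_type)),
      type = rep(types, each = cells_per_type))
    is_csm <- runif(n_loci) < frac_csm
    levels <- matrix(NA_real_, n_loci, n_types,
                     dimnames = list(NULL, types))
    hyper_sets <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      if (is_csm[i]) {
        n_hyper <- sample.int(n_types - 1L, 1L)
        hyper <- sample.int(n_types, n_hyper)
        for (try in 1:100) {
          lv_hi <- rbeta(n_hyper, hyper_shape[1], hyper_shape[2])
          lv_lo <- rbeta(n_types - n_hyper, hypo_shape[1], hypo_shape[2])
          if (min(lv_hi) - max(lv_lo) > min_planted_diff) break
        }
        levels[i, hyper] <- lv_hi
        levels[i, -hyper] <- lv_lo
        hyper_sets[[i]] <- types[sort(hyper)]
      } else {
        levels[i, ] <- rbeta(1, noncsm_shape[1], noncsm_shape[2])
        hyper_sets[[i]] <- character()
      }
    }
    # coverage: one row per covered (cell, locus, read)
    n_cells <- nrow(cells)
    cov <- matrix(runif(n_loci * n_cells) < cover_rate, n_loci, n_cells)
    hit <- which(cov, arr.ind = TRUE)
    if (depth > 1L) {
      hit <- hit[rep(seq_len(nrow(hit)), each = depth), , drop = FALSE]
    }
    li <- hit[, 1]
    ci <- hit[, 2]
    lv <- levels[cbind(li, match(cells$type[ci], types))]
    calls <- matrix(as.integer(runif(length(lv) * 4L) <
                               rep(lv, times = 4L)), ncol = 4L)
    reads <- read_calls(
      unit_id = cells$cell_id[ci],
      chrom = chrom[li],
      pos = lapply(seq_along(li), function(r) pos[li[r], ]),
      calls = lapply(seq_len(nrow(calls)), function(r) calls[r, ]))
    loci_dt <- data.table(
      locus = locus_id(chrom, p1, p1 + 77L),
      chrom = chrom, start = p1, end = p1 + 77L,
      p1 = pos[, 1], p2 = pos[, 2], p3 = pos[, 3], p4 = pos[, 4],
      is_csm = is_csm, hyper_types = hyper_sets)
    list(reads = reads,
         truth = list(loci = loci_dt, levels = levels, cells = cells))
  })
}

#' Per-cell methylation counts within loci
#'
#' Assigns each read to the locus overlapping its span and pools its site
#' calls, giving per unit (cell or read id) and locus the methylated and
#' total call counts.
#'
#' @param reads a `read_calls` object.
#' @param loci loci table with `chrom`, `start`, `end`.
#' @return `data.table` with `unit_id`, `locus`, `meth`, `total`.
#' @export
locus_level_counts <- function(reads, loci) {
  loci <- as.data.table(loci)
  span_start <- vapply(reads$pos, function(p) p[1], integer(1))
  span_end <- vapply(reads$pos, function(p) p[length(p)], integer(1)) + 2L
  gr_reads <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(start = span_start + 1L, end = span_end))
  gr_loci <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  ov <- GenomicRanges::findOverlaps(gr_reads, gr_loci)
  qi <- S4Vectors::queryHits(ov)
  dt <- data.table(
    unit_id = reads$unit_id[qi],
    locus = locus_id(loci$chrom, loci$start,
                     loci$end)[S4Vectors::subjectHits(ov)],
    meth = vapply(reads$calls[qi], sum, integer(1)),
    total = lengths(reads$calls[qi]))
  dt[, list(meth = sum(meth), total = sum(total)), by = c("unit_id", "locus")]
}

#' Merge cell profiles into reference methylomes
#'
#' Per cell type and locus, methylated and total calls are pooled over the
#' type's cells; the reference level is the pooled methylated fraction.
#'
#' @param counts per-cell locus counts ([locus_level_counts()] output):
#'   `unit_id`, `locus`, `meth`, `total`.
#' @param cell_types `data.table` with `cell_id`, `type`.
#' @return list with `levels` (loci x types matrix, NA where a type has no
#'   calls) and `coverage` (total calls, same shape).
#' @export
merge_reference <- function(counts, cell_types) {
  ct <- as.data.table(cell_types)
  if (any(!counts$unit_id %in% ct$cell_id)) {
    stop("counts contain unit ids without a cell-type label")
  }
  types <- sort(unique(ct$type))
  empty <- setdiff(types, ct[cell_id %in% counts$unit_id, unique(type)])
  if (length(empty)) stop("cell type(s) with zero covered cells: ",
                          paste(empty, collapse = ", "))
  x <- merge(counts, ct, by.x = "unit_id", by.y = "cell_id")
  agg <- x[, list(meth = sum(meth), total = sum(total)),
           by = c("locus", "type")]
  loci <- sort(unique(agg$locus))
  lev <- matrix(NA_real_, length(loci), length(types),
                dimnames = list(loci, types))
  cov <- matrix(0, length(loci), length(types),
                dimnames = list(loci, types))
  ij <- cbind(match(agg$locus, loci), match(agg$type, types))
  lev[ij] <- agg$meth / agg$total
  cov[ij] <- agg$total
  list(levels = lev, coverage = cov)
}

# one Dirichlet(1, ..., 1) draw per column
rdirichlet_flat <- function(n_types, n_samples) {
  g <- matrix(rgamma(n_types * n_samples, shape = 1), n_types, n_samples)
  sweep(g, 2, colSums(g), "/")
}

#' Synthesize cell mixtures with known proportions
#'
#' Proportions are drawn from a flat Dirichlet (uniform marginals over the
#' simplex), or supplied. Mixing is coverage-weighted in level space:
#' `level = sum_t p_t c_t m_t / sum_t p_t c_t`, which reduces to the plain
#' convex combination `sum_t p_t m_t` for equal coverage. Optional
#' binomial read-resampling noise at `resample_depth` calls per locus.
#'
#' @param ref_levels loci x types reference level matrix (complete).
#' @param coverage loci x types coverage matrix, or `NULL` for equal.
#' @param n_samples number of synthetic methylomes.
#' @param proportions optional types x samples matrix (columns on the
#'   simplex) overriding the Dirichlet draw.
#' @param resample_depth if non-`NULL`, each level is replaced by
#'   `Binomial(resample_depth, level) / resample_depth`.
#' @param seed integer seed.
#' @return list with `matrix` (loci x samples), `truth` (`data.table` of
#'   `sample_id`, `reference`, `proportion`), `proportions`
#'   (types x samples), `seed`.
#' @export
synthesize_mixtures <- function(ref_levels, coverage = NULL, n_samples = 100L,
                                proportions = NULL, resample_depth = NULL,
                                seed = NULL) {
  stopifnot(!anyNA(ref_levels))
  n_types <- ncol(ref_levels)
  with_seed(seed, {
    P <- if (is.null(proportions)) rdirichlet_flat(n_types, n_samples)
         else proportions
    stopifnot(nrow(P) == n_types,
              all(abs(colSums(P) - 1) < 1e-8))
    n_samples <- ncol(P)
    C <- if (is.null(coverage)) matrix(1, nrow(ref_levels), n_types)
         else coverage
    stopifnot(all(dim(C) == dim(ref_levels)))
    num <- (ref_levels * C) %*% P
    den <- C %*% P
    M <- num / den
    if (!is.null(resample_depth)) {
      M[] <- rbinom(length(M), resample_depth, as.vector(M)) / resample_depth
    }
    sample_ids <- sprintf("mix%03d", seq_len(n_samples))
    colnames(M) <- sample_ids
    rownames(M) <- rownames(ref_levels)
    rownames(P) <- colnames(ref_levels)
    colnames(P) <- sample_ids
    truth <- data.table(
      sample_id = rep(sample_ids, each = n_types),
      reference = rep(colnames(ref_levels), times = n_samples),
      proportion = as.vector(P))
    list(matrix = M, truth = truth, proportions = P, seed = seed)
  })
}

#' Select highly variable CpG sites
#'
#' The baseline feature set for dissection: the `n` sites with maximal
#' sample-to-sample variance, ties broken by row (coordinate) order.
#'
#' @param m sites x samples level matrix.
#' @param n number of sites to keep.
#' @return row-name subset (or indices when unnamed), ordered by
#'   decreasing variance.
#' @export
select_hvar_cpgs <- function(m, n) {
  v <- apply(m, 1, var)
  if (n > nrow(m)) {
    warning("n exceeds available sites; returning all")
    n <- nrow(m)
  }
  ord <- order(-v, seq_along(v))
  idx <- ord[seq_len(n)]
  if (!is.null(rownames(m))) rownames(m)[idx] else idx
}

#' Root-mean-square error
#'
#' `sqrt(sum((m - m_hat)^2) / N)` over `N` paired loci.
#'
#' @param m,m_hat equal-length numeric vectors.
#' @return scalar RMSE.
#' @export
rmse <- function(m, m_hat) {
  if (length(m) != length(m_hat)) stop("length mismatch")
  stopifnot(length(m) >= 1L)
  sqrt(sum((m - m_hat)^2) / length(m))
}

#' Mean absolute error of mixing proportions
#'
#' `sum_i |p_i - p_hat_i| / n_types` over all reference types; estimates
#' for types without a matched component are set to zero. The denominator
#' is the number of reference types (16 in a 16-type study), not the
#' number of matched components.
#'
#' @param p_true named numeric vector of true proportions (one per type).
#' @param p_est named numeric vector of estimated proportions for matched
#'   types; missing names count as zero.
#' @param n_types denominator; defaults to `length(p_true)`.
#' @return scalar MAE.
#' @export
mae <- function(p_true, p_est, n_types = length(p_true)) {
  est <- setNames(numeric(length(p_true)), names(p_true))
  keep <- intersect(names(p_est), names(p_true))
  est[keep] <- p_est[keep]
  sum(abs(p_true - est)) / n_types
}

#' Score a dissection against known truth
#'
#' Matches LMCs to references ([match_lmcs()]), computes the RMSE between
#' each matched LMC profile and its reference, and the proportion MAE per
#' sample (unmatched types scored as zero, denominator = number of
#' reference types).
#'
#' @param W loci x k fitted profile matrix.
#' @param H k x samples fitted proportion matrix.
#' @param ref_levels loci x types reference matrix (same loci as `W`).
#' @param truth `data.table` with `sample_id`, `reference`, `proportion`.
#' @return an `evaluation_report`: list with `assignment`, `rmse` (named
#'   per matched reference), `mae` (mean over samples), `mae_per_sample`,
#'   `n_correct`.
#' @export
evaluate_dissection <- function(W, H, ref_levels, truth) {
  assignment <- match_lmcs(W, ref_levels)
  pairs <- assignment$pairs
  rmse_by_ref <- setNames(
    vapply(seq_len(nrow(pairs)), function(i) {
      common <- intersect(rownames(W), rownames(ref_levels))
      rmse(ref_levels[common, pairs$reference[i]], W[common, pairs$lmc[i]])
    }, numeric(1)),
    pairs$reference)
  truth <- as.data.table(truth)
  types <- sort(unique(truth$reference))
  samples <- colnames(H)
  if (is.null(samples)) samples <- unique(truth$sample_id)
  mae_s <- vapply(samples, function(s) {
    tt <- truth[sample_id == s]
    p_true <- setNames(tt$proportion, tt$reference)[types]
    p_est <- setNames(H[pairs$lmc, s], pairs$reference)
    mae(p_true, p_est, n_types = length(types))
  }, numeric(1))
  out <- list(assignment = assignment, rmse = rmse_by_ref,
              mae = mean(mae_s), mae_per_sample = mae_s,
              n_correct = nrow(pairs))
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("dissection evaluation: %d matched component(s), MAE = %.4f\n",
              x$n_correct, x$mae))
  if (length(x$rmse)) {
    cat("  per-reference RMSE:\n")
    for (nm in names(x$rmse)) cat(sprintf("    %s: %.4f\n", nm, x$rmse[nm]))
  }
  invisible(x)
}

#' Write / read a mixture truth table
#'
#' TSV with columns `sample_id`, `reference`, `proportion`.
#'
#' @param truth truth `data.table`.
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  fwrite(as.data.table(truth), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  fread(path, sep = "\t", header = TRUE)
}
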