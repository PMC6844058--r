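# End-to-end convenience wrappers: synthetic single cells -> pCSM calls
# -> references and mixtures -> co-methylation/eigen loci -> NMF -> scores.

#' Call pCSM loci from a read-pattern dataset
#'
#' Chains segment extraction, filtering, bipolarity calling and interval
#' merging.
#'
#' @param reads a `read_calls` object.
#' @param mode `"single_cell"` or `"bulk"`.
#' @param blacklist optional `GRanges` or BED path.
#' @param min_cov minimum segment coverage.
#' @param autosomes_only restrict to autosomes.
#' @param alpha,min_diff,p_method,B,seed passed to [call_pcsm()].
#' @return list with `calls` (per-segment table), `loci` (merged pCSM
#'   loci), `segments` (filtered profiles).
#' @export
find_pcsm_loci <- function(reads, mode = c("single_cell", "bulk"),
                           blacklist = NULL, min_cov = 10L,
                           autosomes_only = TRUE, alpha = 0.05,
                           min_diff = 0.30,
                           p_method = c("bootstrap", "chisq"), B = 200L,
                           seed = 0L) {
  mode <- match.arg(mode)
  p_method <- match.arg(p_method)
  segs <- extract_segments(reads, mode = mode)
  segs <- filter_segments(segs, blacklist = blacklist, min_cov = min_cov,
                          autosomes_only = autosomes_only)
  calls <- call_pcsm(segs, alpha = alpha, min_diff = min_diff,
                     p_method = p_method, B = B, seed = seed)
  loci <- merge_to_loci(calls[calls$is_pcsm])
  list(calls = calls, loci = loci, segments = segs)
}

#' Synthetic mixture dissection study
#'
#' Runs the whole pipeline on a synthetic single-cell dataset: pCSM locus
#' discovery, reference merging by true cell type, Dirichlet mixture
#' synthesis, co-methylation eigen-locus selection, NMF at `k = n_types`,
#' component matching and scoring.
#'
#' @param sim output of [generate_synthetic_cells()].
#' @param n_samples synthetic mixtures to draw.
#' @param lambda binarization penalty for the factorization.
#' @param eigen_fraction per-module eigen-locus fraction. The default is
#'   larger than the 0.10 used for display purposes because a
#'   k-component factorization needs on the order of tens of loci per
#'   component; the eigen set is additionally topped up with
#'   highly variable loci to at least `10 * n_types` loci.
#' @param kmeans_k methylation-level groups before network clustering.
#' @param min_module_size minimum co-methylation module size.
#' @param n_restarts NMF restarts.
#' @param min_cov,alpha,min_diff,p_method,B pCSM-calling parameters.
#' @param seed integer seed for every stochastic stage.
#' @return list with `evaluation` (an `evaluation_report`), `fit`
#'   (`lmc_result`), `mixtures`, `references`, `pcsm`, `eigen_loci`.
#' @export
dissect_mixture_study <- function(sim, n_samples = 100L, lambda = 1e-4,
                                  eigen_fraction = 0.25, kmeans_k = 3L,
                                  min_module_size = 30L, n_restarts = 10L,
                                  min_cov = 10L, alpha = 0.05,
                                  min_diff = 0.30,
                                  p_method = c("bootstrap", "chisq"),
                                  B = 200L, seed = 1L) {
  p_method <- match.arg(p_method)
  pcsm <- find_pcsm_loci(sim$reads, mode = "single_cell", min_cov = min_cov,
                         alpha = alpha, min_diff = min_diff,
                         p_method = p_method, B = B, seed = seed)
  if (nrow(pcsm$loci) < 10L) stop("too few pCSM loci discovered")
  counts <- locus_level_counts(sim$reads, pcsm$loci)
  refs <- merge_reference(counts, sim$truth$cells)
  complete <- rowSums(is.na(refs$levels)) == 0L
  ref_levels <- refs$levels[complete, , drop = FALSE]
  ref_cov <- refs$coverage[complete, , drop = FALSE]
  n_types <- ncol(ref_levels)
  mix <- synthesize_mixtures(ref_levels, coverage = ref_cov,
                             n_samples = n_samples, seed = seed + 1L)
  cometh <- run_comethylation(mix$matrix, k = kmeans_k,
                              fraction = eigen_fraction,
                              min_module_size = min_module_size,
                              seed = seed + 2L)
  eigen <- cometh$eigen_loci
  min_eigen <- min(10L * n_types, nrow(mix$matrix))
  if (length(eigen) < min_eigen) {
    # a k-component fit needs tens of loci per component: top up the
    # eigen set with the most variable remaining loci
    extra <- suppressWarnings(select_hvar_cpgs(mix$matrix, min_eigen))
    eigen <- union(eigen, setdiff(extra, eigen)[
      seq_len(min_eigen - length(eigen))])
  }
  fit <- factorize(mix$matrix[eigen, , drop = FALSE], k = n_types,
                   lambda = lambda, n_restarts = n_restarts,
                   seed = seed + 3L)
  evaluation <- evaluate_dissection(fit$W, fit$H,
                                    ref_levels[eigen, , drop = FALSE],
                                    mix$truth)
  list(evaluation = evaluation, fit = fit, mixtures = mix,
       references = list(levels = ref_levels, coverage = ref_cov),
       pcsm = pcsm, eigen_loci = eigen, comethylation = cometh)
}
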