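# annotation: fold enrichment of pCSM loci across genomic features
# against length-matched random control regions.

#' Derive flanking feature sets (shores and shelves)
#'
#' Shores are the `width` bp immediately outside each interval, shelves
#' the `width` bp outside the shores; parent intervals (and, for shelves,
#' shores) are subtracted so the sets are disjoint, and flanks are clamped
#' at position 0.
#'
#' @param features a `GRanges` of base intervals (e.g. CpG islands).
#' @param width flank width in bp.
#' @return list with `shores` and `shelves`, both `GRanges`.
#' @export
derive_flanks <- function(features, width = 2000L) {
  base <- GenomicRanges::reduce(features)
  both_flanks <- function(gr, w) {
    left <- GenomicRanges::flank(gr, w, start = TRUE)
    right <- GenomicRanges::flank(gr, w, start = FALSE)
    out <- GenomicRanges::reduce(c(left, right))
    GenomicRanges::restrict(out, start = 1L)
  }
  shores <- GenomicRanges::setdiff(both_flanks(base, width), base)
  inner <- GenomicRanges::reduce(c(base, shores))
  shelves <- GenomicRanges::setdiff(both_flanks(inner, width), inner)
  list(shores = shores, shelves = shelves)
}

# random length-matched placement of loci on autosomes, avoiding the
# blacklist by rejection
random_controls <- function(widths, chrom_sizes, blacklist = NULL,
                            max_tries = 50L) {
  chroms <- names(chrom_sizes)
  stopifnot(length(chroms) > 0L)
  auto <- chroms[is_autosome(chroms)]
  if (length(auto)) {
    chroms <- auto
    chrom_sizes <- chrom_sizes[auto]
  }
  pick <- sample(chroms, length(widths), replace = TRUE,
                 prob = chrom_sizes / sum(chrom_sizes))
  room <- pmax(chrom_sizes[pick] - widths, 1)
  start <- floor(runif(length(widths)) * room)
  gr <- GenomicRanges::GRanges(
    pick, IRanges::IRanges(start = start + 1L, width = widths))
  if (!is.null(blacklist) && length(blacklist)) {
    for (t in seq_len(max_tries)) {
      bad <- IRanges::overlapsAny(gr, blacklist)
      if (!any(bad)) break
      nb <- sum(bad)
      pick2 <- sample(chroms, nb, replace = TRUE,
                      prob = chrom_sizes / sum(chrom_sizes))
      room2 <- pmax(chrom_sizes[pick2] - widths[bad], 1)
      gr[bad] <- GenomicRanges::GRanges(
        pick2, IRanges::IRanges(start = floor(runif(nb) * room2) + 1L,
                                width = widths[bad]))
    }
  }
  gr
}

#' Fold enrichment of loci across genomic features
#'
#' For each feature set, the fraction of loci with at least 1 bp overlap
#' (each locus counted once) is compared to the mean fraction over
#' `n_control_draws` random length-matched placements on the autosomes of
#' the supplied genome, excluding the blacklist. The empirical interval is
#' the observed fraction divided by the 97.5 and 2.5 percent quantiles of
#' the control fractions.
#'
#' @param loci a `GRanges`, or a loci `data.table` (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param features named list of `GRanges` feature sets.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param blacklist optional `GRanges` that controls must avoid.
#' @param n_control_draws number of control placements.
#' @param seed integer seed.
#' @return `data.table` with `feature`, `n_loci_hit`, `frac`, `fold`,
#'   `ci_low`, `ci_high`; `fold` is `Inf` (flagged by `infinite_fold`)
#'   when no control ever hits the feature.
#' @export
fold_enrichment <- function(loci, features, chrom_sizes, blacklist = NULL,
                            n_control_draws = 100L, seed = NULL) {
  if (!inherits(loci, "GRanges")) {
    dt <- as.data.table(loci)
    loci <- GenomicRanges::GRanges(
      dt$chrom, IRanges::IRanges(start = dt$start + 1L, end = dt$end))
  }
  if (length(features) == 0L) {
    return(data.table(feature = character(), n_loci_hit = integer(),
                      frac = numeric(), fold = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      infinite_fold = logical()))
  }
  stopifnot(!is.null(names(features)), length(loci) > 0L)
  widths <- GenomicRanges::width(loci)
  with_seed(seed, {
    obs <- vapply(features, function(f) {
      mean(IRanges::overlapsAny(loci, f))
    }, numeric(1))
    ctrl <- matrix(NA_real_, n_control_draws, length(features),
                   dimnames = list(NULL, names(features)))
    for (d in seq_len(n_control_draws)) {
      g <- random_controls(widths, chrom_sizes, blacklist)
      ctrl[d, ] <- vapply(features, function(f) {
        mean(IRanges::overlapsAny(g, f))
      }, numeric(1))
    }
    ctrl_mean <- colMeans(ctrl)
    fold <- ifelse(ctrl_mean > 0, obs / ctrl_mean, Inf)
    qs <- apply(ctrl, 2, quantile, probs = c(0.975, 0.025))
    data.table(
      feature = names(features),
      n_loci_hit = as.integer(round(obs * length(loci))),
      frac = obs,
      fold = fold,
      ci_low = ifelse(qs[1, ] > 0, obs / qs[1, ], Inf),
      ci_high = ifelse(qs[2, ] > 0, obs / qs[2, ], Inf),
      infinite_fold = !is.finite(fold))
  })
}
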