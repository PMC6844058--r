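# pcsm: candidate gating and bipolarity calling of 4-CpG segments.
#
# A segment is a pCSM candidate when at least one unit is completely
# methylated ("1111") and another completely unmethylated ("0000").
# Candidates are split into hypomethylated and hypermethylated unit
# subsets (beta-mixture responsibilities in single-cell mode, DP pattern
# clustering in bulk mode) and called pCSM when the subset methylation
# difference exceeds `min_diff` and the BH-adjusted bipolarity p-value is
# below `alpha`.

#' Candidate gate: bipolar pattern presence
#'
#' @param patterns character vector of 4-bit patterns observed at one
#'   segment (one per unit).
#' @return `TRUE` iff both `"1111"` and `"0000"` are present.
#' @export
is_candidate <- function(patterns) {
  any(patterns == "1111") && any(patterns == "0000")
}

#' Per-unit methylation levels of a segment
#'
#' @param patterns character vector of 4-bit patterns.
#' @return numeric vector: methylated-site fraction per unit, in
#'   `{0, 0.25, 0.5, 0.75, 1}`.
#' @export
unit_levels <- function(patterns) {
  vapply(strsplit(patterns, "", fixed = TRUE),
         function(s) mean(s == "1"), numeric(1))
}

#' Call pCSM segments
#'
#' For every segment: non-candidates are reported with `p_raw = p_adj = 1`
#' and `is_pcsm = FALSE`. Candidates are fitted with the beta mixture
#' ([fit_beta_mixture()]) on unit levels; in bulk mode the unit partition
#' comes from DP pattern clustering ([cluster_patterns_bulk()]) instead of
#' mixture responsibilities. Subset means are hard-assignment means of the
#' raw unit levels. Raw p-values from [test_bipolarity()] are adjusted by
#' Benjamini-Hochberg across tested candidates only.
#'
#' @param profiles a `segment_profiles` object (already filtered).
#' @param alpha FDR threshold on adjusted p-values.
#' @param min_diff minimum hyper-minus-hypo methylation difference.
#' @param p_method,B passed to [test_bipolarity()].
#' @param seed integer; per-segment seeds are derived deterministically
#'   from the segment key offset by this value.
#' @param mode overrides the mode attribute of `profiles`.
#' @return a `data.table` with one row per segment: key columns, `coverage`,
#'   `mu_hypo`, `mu_hyper`, `diff`, `p_raw`, `p_adj`, `is_pcsm`,
#'   `converged`, plus list-columns `hypo_units`, `hyper_units`.
#' @export
call_pcsm <- function(profiles, alpha = 0.05, min_diff = 0.30,
                      p_method = c("bootstrap", "chisq"), B = 200L,
                      seed = 0L, mode = NULL) {
  p_method <- match.arg(p_method)
  if (is.null(mode)) mode <- attr(profiles, "mode")
  if (is.null(mode)) mode <- "single_cell"
  dt <- as.data.table(profiles)
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), p1 = integer(), p2 = integer(),
                      p3 = integer(), p4 = integer(), coverage = integer(),
                      mu_hypo = numeric(), mu_hyper = numeric(),
                      diff = numeric(), p_raw = numeric(), p_adj = numeric(),
                      is_pcsm = logical(), converged = logical(),
                      hypo_units = list(), hyper_units = list()))
  }
  res <- dt[, {
    lv <- unit_levels(pattern)
    key <- segment_key(chrom[1], p1, p2, p3, p4)
    sd_seed <- seed_from_key(key, seed)
    if (!is_candidate(pattern)) {
      list(coverage = .N, mu_hypo = NA_real_, mu_hyper = NA_real_,
           diff = NA_real_, p_raw = 1, candidate = FALSE, converged = TRUE,
           hypo_units = list(character()), hyper_units = list(character()))
    } else {
      fit <- fit_beta_mixture(lv, n_sites = 4L, seed = sd_seed)
      part <- if (mode == "bulk") {
        dp <- cluster_patterns_bulk(pattern, seed = sd_seed)
        dp_to_subsets(dp$assignment, lv)
      } else {
        mixture_partition(fit)
      }
      if (length(unique(part)) < 2L) {
        # single subset identified: no difference measurable
        list(coverage = .N, mu_hypo = mean(lv), mu_hyper = mean(lv),
             diff = 0, p_raw = 1, candidate = TRUE,
             converged = isTRUE(fit$converged),
             hypo_units = list(unit_id), hyper_units = list(character()))
      } else {
        mu <- tapply(lv, part, mean)
        p <- test_bipolarity(fit, method = p_method, B = B,
                             seed = sd_seed + 1L)
        list(coverage = .N, mu_hypo = unname(mu["1"]),
             mu_hyper = unname(mu["2"]), diff = unname(mu["2"] - mu["1"]),
             p_raw = p, candidate = TRUE,
             converged = isTRUE(fit$converged),
             hypo_units = list(unit_id[part == 1L]),
             hyper_units = list(unit_id[part == 2L]))
      }
    }
  }, by = c("chrom", "p1", "p2", "p3", "p4")]
  res[, p_adj := 1]
  tested <- which(res$candidate)
  if (length(tested)) {
    res$p_adj[tested] <- p.adjust(res$p_raw[tested], method = "BH")
  }
  res[, is_pcsm := candidate & converged & !is.na(diff) &
        diff > min_diff & p_adj < alpha]
  res[, candidate := NULL]
  setorder(res, chrom, p1)
  res[]
}

#' Mean level and subset difference per segment
#'
#' For every segment (pCSM or not) computes the overall mean unit level
#' and the hypo/hyper subset methylation difference. Segments whose units
#' all share one level (e.g. all fully methylated) admit only one subset
#' and get `diff = 0`; other segments are split by the beta-mixture hard
#' assignment.
#'
#' @param profiles a `segment_profiles` object.
#' @param seed integer seed offset (as in [call_pcsm()]).
#' @return `data.table` with key columns, `mean_level`, `diff`.
#' @export
subset_diff_stats <- function(profiles, seed = 0L) {
  dt <- as.data.table(profiles)
  dt[, {
    lv <- unit_levels(pattern)
    if (length(unique(lv)) < 2L) {
      list(mean_level = mean(lv), diff = 0)
    } else {
      key <- segment_key(chrom[1], p1, p2, p3, p4)
      fit <- fit_beta_mixture(lv, n_sites = 4L,
                              seed = seed_from_key(key, seed))
      part <- mixture_partition(fit)
      if (length(unique(part)) < 2L) {
        list(mean_level = mean(lv), diff = 0)
      } else {
        mu <- tapply(lv, part, mean)
        list(mean_level = mean(lv), diff = unname(mu["2"] - mu["1"]))
      }
    }
  }, by = c("chrom", "p1", "p2", "p3", "p4")]
}

#' Write a pCSM call table
#'
#' @param calls output of [call_pcsm()].
#' @param path output TSV path.
#' @export
write_pcsm_table <- function(calls, path) {
  out <- as.data.table(calls)[, c("chrom", "p1", "p2", "p3", "p4",
                                  "coverage", "mu_hypo", "mu_hyper", "diff",
                                  "p_raw", "p_adj", "is_pcsm")]
  fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
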