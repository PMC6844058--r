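# comethy: co-methylation analysis of pCSM loci across many methylomes.
#
# Two-stage clustering: k-means splits loci into hypo/mid/hypermethylated
# groups; within each group a signed weighted co-methylation network
# (adjacency ((1 + cor)/2)^power, topological overlap, average-linkage
# clustering, fixed-height cut with small-module absorption) yields
# modules, and PCA picks each module's representative eigen-pCSM loci.

#' Build a loci-by-samples methylation matrix
#'
#' Per sample and locus, the methylation level is the methylated-call
#' fraction over all CpG calls falling inside the locus. Loci covered in
#' fewer than `min_samples_covered` samples are dropped; remaining missing
#' entries are imputed with the locus mean and flagged.
#'
#' @param loci loci `data.table` (`chrom`, `start`, `end`) as produced by
#'   [merge_to_loci()].
#' @param site_counts long-format per-sample CpG counts: a `data.table`
#'   with columns `sample_id`, `chrom`, `pos` (0-based C position),
#'   `meth` (methylated calls), `total` (total calls).
#' @param min_samples_covered minimum samples with data for a locus.
#' @return numeric matrix, loci (named `"chrom:start-end"`) by samples,
#'   with a logical attribute `"imputed"` marking filled-in entries.
#' @export
build_matrix <- function(loci, site_counts, min_samples_covered = 1L) {
  loci <- as.data.table(loci)
  sc <- as.data.table(site_counts)
  gr_loci <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  gr_site <- GenomicRanges::GRanges(
    sc$chrom, IRanges::IRanges(start = sc$pos + 1L, width = 2L))
  ov <- GenomicRanges::findOverlaps(gr_site, gr_loci)
  hits <- sc[S4Vectors::queryHits(ov)]
  hits[, locus := locus_id(loci$chrom, loci$start, loci$end)[S4Vectors::subjectHits(ov)]]
  agg <- hits[, list(level = sum(meth) / sum(total)), by = c("locus", "sample_id")]
  samples <- sort(unique(sc$sample_id))
  ids <- locus_id(loci$chrom, loci$start, loci$end)
  m <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  m[cbind(match(agg$locus, ids), match(agg$sample_id, samples))] <- agg$level
  covered <- rowSums(!is.na(m))
  m <- m[covered >= min_samples_covered, , drop = FALSE]
  if (nrow(m) == 0L) stop("no locus covered in at least ",
                          min_samples_covered, " samples")
  imputed <- is.na(m)
  if (any(imputed)) {
    rm_ <- rowMeans(m, na.rm = TRUE)
    idx <- which(imputed, arr.ind = TRUE)
    m[idx] <- rm_[idx[, 1]]
  }
  attr(m, "imputed") <- imputed
  m
}

#' Partition loci into methylation-level groups by k-means
#'
#' @param m methylation matrix (loci x samples).
#' @param k number of groups (default 3: hypo/mid/hyper).
#' @param seed integer seed.
#' @param max_restarts re-seeded restarts on an empty-cluster failure.
#' @return named list of row-index vectors, ordered (and for `k = 3`
#'   named `hypo`/`mid`/`hyper`) by ascending group mean level.
#' @export
kmeans_partition <- function(m, k = 3L, seed = NULL, max_restarts = 10L) {
  stopifnot(k >= 1L, nrow(m) >= k)
  if (k == 1L) {
    out <- list(all = seq_len(nrow(m)))
    return(out)
  }
  with_seed(seed, {
    km <- NULL
    for (r in seq_len(max_restarts)) {
      km <- tryCatch(kmeans(m, centers = k, nstart = 5L, iter.max = 50L),
                     error = function(e) NULL,
                     warning = function(w) NULL)
      if (!is.null(km) && all(km$size > 0L)) break
    }
    if (is.null(km)) stop("k-means failed to produce ", k, " non-empty groups")
    ord <- order(rowMeans(km$centers))
    groups <- lapply(ord, function(g) which(km$cluster == g))
    names(groups) <- if (k == 3L) c("hypo", "mid", "hyper")
                     else paste0("group", seq_len(k))
    groups
  })
}

# signed adjacency from a correlation matrix
signed_adjacency <- function(cmat, power) {
  ((1 + cmat) / 2)^power
}

# scale-free topology fit index: R-squared of log10 p(k) on log10 k over
# equal-occupancy connectivity bins, zeroed when the slope is positive
scale_free_r2 <- function(connectivity, n_bins = 10L) {
  kk <- connectivity[connectivity > 0]
  if (length(unique(kk)) < 3L) return(0)
  brk <- unique(quantile(kk, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(brk) < 3L) return(0)
  bin <- cut(kk, breaks = brk, include.lowest = TRUE)
  dk <- tapply(kk, bin, mean)
  pk <- tapply(kk, bin, length) / length(kk)
  ok <- !is.na(dk) & !is.na(pk) & pk > 0 & dk > 0
  if (sum(ok) < 3L) return(0)
  lk <- log10(dk[ok])
  lp <- log10(pk[ok])
  if (sd(lk) < 1e-12 || sd(lp) < 1e-12) return(0)
  r <- cor(lp, lk)
  if (!is.finite(r) || r > 0) return(0)  # positive slope: not scale-free
  r^2
}

#' Choose the soft-thresholding power
#'
#' Scans candidate powers for the signed adjacency
#' `((1 + cor)/2)^power` and returns the smallest power whose scale-free
#' topology fit R-squared reaches `r2_target`; if none does, the power
#' with the maximal R-squared.
#'
#' @param m methylation matrix (loci x samples), at least 3 samples.
#' @param powers candidate integer powers.
#' @param r2_target scale-free fit target.
#' @return list with `power` (chosen), `fit` (`data.table` of power,
#'   r_squared, mean connectivity).
#' @export
pick_soft_threshold <- function(m, powers = 1:20, r2_target = 0.8) {
  stopifnot(ncol(m) >= 3L)
  v <- apply(m, 1, var)
  if (any(v < 1e-12)) stop("zero variance loci")
  cmat <- cor(t(m), use = "pairwise.complete.obs")
  fit <- rbindlist(lapply(powers, function(p) {
    a <- signed_adjacency(cmat, p)
    diag(a) <- 0
    kk <- rowSums(a)
    data.table(power = p, r_squared = scale_free_r2(kk),
               mean_connectivity = mean(kk))
  }))
  ok <- fit$r_squared >= r2_target
  power <- if (any(ok)) fit$power[which(ok)[1]]
           else fit$power[which.max(fit$r_squared)]
  list(power = power, fit = fit)
}

# topological overlap similarity of a (signed) adjacency matrix
tom_similarity <- function(a) {
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect signed co-methylation modules
#'
#' Builds the signed adjacency at `soft_power` (negatively correlated
#' locus pairs get near-zero adjacency), transforms it to topological
#' overlap, clusters the TOM dissimilarity by average-linkage and cuts the
#' dendrogram at `cut_height_frac` of its height. Clusters smaller than
#' `min_module_size` are absorbed into the nearest large module when the
#' correlation of their mean profiles exceeds `absorb_cor`, otherwise they
#' go to the unassigned pool.
#'
#' @param m methylation matrix (loci x samples).
#' @param soft_power soft-thresholding power (see [pick_soft_threshold()]).
#' @param min_module_size minimum module size.
#' @param cut_height_frac fixed cut height as a fraction of the dendrogram
#'   height.
#' @param absorb_cor minimum module-mean correlation for absorption.
#' @return a `cometh_modules` object: list with `modules` (named list of
#'   locus-id vectors), `unassigned` (locus ids), `soft_power`.
#' @export
detect_modules <- function(m, soft_power, min_module_size = 30L,
                           cut_height_frac = 0.995, absorb_cor = 0.75) {
  ids <- rownames(m)
  if (nrow(m) < 2L) {
    out <- list(modules = if (nrow(m) >= 1L) list(M1 = ids) else list(),
                unassigned = character(), soft_power = soft_power)
    class(out) <- "cometh_modules"
    return(out)
  }
  cmat <- cor(t(m), use = "pairwise.complete.obs")
  cmat[is.na(cmat)] <- 0
  a <- signed_adjacency(cmat, soft_power)
  diss <- 1 - tom_similarity(a)
  hc <- hclust(stats::as.dist(diss), method = "average")
  cl <- cutree(hc, h = cut_height_frac * max(hc$height))
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= min_module_size])
  small <- setdiff(as.integer(names(sizes)), big)
  assign <- cl
  if (length(big) && length(small)) {
    means_big <- vapply(big, function(g) colMeans(m[cl == g, , drop = FALSE]),
                        numeric(ncol(m)))
    for (g in small) {
      mg <- colMeans(m[cl == g, , drop = FALSE])
      cc <- suppressWarnings(cor(mg, means_big))
      cc[is.na(cc)] <- -1
      if (max(cc) > absorb_cor) {
        assign[cl == g] <- big[which.max(cc)]
      } else {
        assign[cl == g] <- 0L
      }
    }
  } else if (length(small)) {
    assign[cl %in% small] <- 0L
  }
  mods <- lapply(big, function(g) ids[assign == g])
  # stable ordering: largest module first
  if (length(mods)) {
    mods <- mods[order(-lengths(mods))]
    names(mods) <- paste0("M", seq_along(mods))
  } else {
    mods <- list()
  }
  out <- list(modules = mods, unassigned = ids[assign == 0L],
              soft_power = soft_power)
  class(out) <- "cometh_modules"
  out
}

#' @export
print.cometh_modules <- function(x, ...) {
  cat("co-methylation modules (power ", x$soft_power, "): ",
      length(x$modules), " modules, ", length(x$unassigned),
      " unassigned loci\n", sep = "")
  for (nm in names(x$modules)) {
    cat("  ", nm, ": ", length(x$modules[[nm]]), " loci\n", sep = "")
  }
  invisible(x)
}

#' Select eigen-pCSM loci of a module
#'
#' PCA is run on the module's centered samples-by-loci matrix; the PC1
#' sign is fixed so that the PC1 sample scores correlate positively with
#' the module mean profile; loci are ranked by absolute PC1 loading and
#' the top `ceil(fraction * module size)` are returned. Modules with fewer
#' than 10 loci return all members (flagged via attribute `"flagged"`).
#'
#' @param members locus ids of the module.
#' @param m methylation matrix containing those loci as rows.
#' @param fraction fraction of members to keep.
#' @return character vector of eigen locus ids, with attributes
#'   `"pc1_var"` (fraction of variance on PC1) and `"loadings"`.
#' @export
select_eigen_loci <- function(members, m, fraction = 0.10) {
  stopifnot(all(members %in% rownames(m)), fraction > 0, fraction <= 1)
  x <- m[members, , drop = FALSE]
  if (length(members) < 10L) {
    out <- members
    attr(out, "flagged") <- TRUE
    return(out)
  }
  y <- scale(t(x), center = TRUE, scale = FALSE)   # samples x loci
  pr <- prcomp(y, center = FALSE)
  load1 <- pr$rotation[, 1]
  score1 <- pr$x[, 1]
  mean_profile <- colMeans(x)                       # per-sample module mean
  s <- suppressWarnings(cor(score1, mean_profile))
  if (!is.na(s) && s < 0) {
    load1 <- -load1
    score1 <- -score1
  }
  n_keep <- ceiling(fraction * length(members))
  out <- members[order(-abs(load1))][seq_len(n_keep)]
  attr(out, "pc1_var") <- unname(pr$sdev[1]^2 / sum(pr$sdev^2))
  attr(out, "loadings") <- load1
  out
}

#' Full co-methylation stage: groups, modules, eigen loci
#'
#' Convenience wrapper chaining [kmeans_partition()],
#' [pick_soft_threshold()], [detect_modules()] and [select_eigen_loci()]
#' per k-means group.
#'
#' @inheritParams kmeans_partition
#' @inheritParams detect_modules
#' @inheritParams select_eigen_loci
#' @param powers,r2_target passed to [pick_soft_threshold()].
#' @return list with `eigen_loci` (character vector over all modules),
#'   `groups` (per-group list of `modules` object and eigen sets),
#'   `assignment` (locus to `group/module` mapping `data.table`).
#' @export
run_comethylation <- function(m, k = 3L, fraction = 0.10,
                              min_module_size = 30L, powers = 1:20,
                              r2_target = 0.8, seed = NULL) {
  groups <- kmeans_partition(m, k = k, seed = seed)
  res <- list()
  eigen_all <- character()
  assign_rows <- list()
  for (gname in names(groups)) {
    sub <- m[groups[[gname]], , drop = FALSE]
    v <- apply(sub, 1, var)
    sub <- sub[v > 1e-12, , drop = FALSE]
    if (nrow(sub) < 2L) next
    st <- pick_soft_threshold(sub, powers = powers, r2_target = r2_target)
    mods <- detect_modules(sub, st$power, min_module_size = min_module_size)
    eig <- lapply(names(mods$modules), function(nm) {
      as.character(select_eigen_loci(mods$modules[[nm]], sub,
                                     fraction = fraction))
    })
    names(eig) <- names(mods$modules)
    res[[gname]] <- list(soft_power = st$power, modules = mods, eigen = eig)
    eigen_all <- c(eigen_all, unlist(eig, use.names = FALSE))
    for (nm in names(mods$modules)) {
      assign_rows[[paste(gname, nm)]] <- data.table(
        locus = mods$modules[[nm]], group = gname, module = nm)
    }
    if (length(mods$unassigned)) {
      assign_rows[[paste(gname, "unassigned")]] <- data.table(
        locus = mods$unassigned, group = gname, module = "unassigned")
    }
  }
  list(eigen_loci = unique(eigen_all), groups = res,
       assignment = rbindlist(assign_rows))
}
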