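# shared fixture builders and independent brute-force oracles

# random read set with c >= 1 called CpGs per read
random_reads <- function(n_reads, seed, max_cpgs = 8L) {
  set.seed(seed)
  unit <- sprintf("r%04d", seq_len(n_reads))
  chrom <- sample(paste0("chr", 1:3), n_reads, replace = TRUE)
  pos <- lapply(seq_len(n_reads), function(i) {
    c_i <- sample.int(max_cpgs, 1L)
    sort(sample.int(500L, c_i)) + 1000L
  })
  calls <- lapply(pos, function(p) rbinom(length(p), 1L, 0.5))
  read_calls(unit, chrom, pos, calls)
}

# independent window enumerator: nested loops, no shared code with
# extract_segments
brute_force_windows <- function(reads) {
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    p <- reads$pos[[i]]
    cl <- reads$calls[[i]]
    if (length(p) < 4L) next
    for (w in seq_len(length(p) - 3L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = reads$chrom[i],
        p1 = p[w], p2 = p[w + 1L], p3 = p[w + 2L], p4 = p[w + 3L],
        unit_id = reads$unit_id[i],
        pattern = paste(cl[w:(w + 3L)], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out[order(out$chrom, out$p1, out$p2, out$p3, out$p4, out$unit_id), ]
}

# segment_profiles table straight from per-segment pattern vectors
profiles_from_patterns <- function(pattern_sets, mode = "single_cell",
                                   chrom = "chr1", spacing = 1000L) {
  rows <- lapply(seq_along(pattern_sets), function(i) {
    pats <- pattern_sets[[i]]
    p1 <- 1000L + (i - 1L) * spacing
    data.table::data.table(
      chrom = chrom, p1 = p1, p2 = p1 + 20L, p3 = p1 + 40L, p4 = p1 + 60L,
      unit_id = sprintf("u%03d", seq_along(pats)), pattern = pats)
  })
  dt <- data.table::rbindlist(rows)
  data.table::setattr(dt, "mode", mode)
  data.table::setattr(dt, "class", c("segment_profiles", class(dt)))
  dt
}

# 4-site patterns for one segment: units at given methylation levels
patterns_at_levels <- function(u) {
  k <- rbinom(length(u), 4L, u)
  vapply(k, function(ki) paste(c(rep("1", ki), rep("0", 4L - ki)),
                               collapse = ""), "")
}

# planted segment set: bipolar segments have two near-complete
# subpopulations (the field's bipolarity definition); unimodal segments
# are a single population with moderate within-population dispersion
make_planted_segments <- function(n_bipolar, n_unimodal, coverage = 40L,
                                  seed = 1L) {
  set.seed(seed)
  pats <- vector("list", n_bipolar + n_unimodal)
  for (i in seq_len(n_bipolar)) {
    w <- runif(1, 0.3, 0.7)
    nh <- rbinom(1, coverage, w)
    u <- c(rbeta(nh, 20, 1), rbeta(coverage - nh, 1, 20))
    pats[[i]] <- patterns_at_levels(u)
  }
  for (i in seq_len(n_unimodal)) {
    m <- runif(1, 0.05, 0.95)
    u <- rbeta(coverage, m * 10, (1 - m) * 10)
    pats[[n_bipolar + i]] <- patterns_at_levels(u)
  }
  profs <- profiles_from_patterns(pats)
  truth <- rep(c(TRUE, FALSE), c(n_bipolar, n_unimodal))
  list(profiles = profs, is_bipolar = truth,
       p1 = 1000L + (seq_along(pats) - 1L) * 1000L)
}

# brute-force evaluation formulas, independent of the package versions
rmse_brute <- function(m, mh) sqrt(mean((m - mh)^2))
mae_brute <- function(p, ph, n_types) {
  s <- 0
  for (nm in names(p)) {
    est <- if (nm %in% names(ph)) ph[[nm]] else 0
    s <- s + abs(p[[nm]] - est)
  }
  s / n_types
}
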