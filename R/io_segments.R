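# io_segments: read-pattern parsing, 4-CpG segment extraction, genomic
# filtering and interval merging.
#
# Coordinates are 0-based half-open throughout. CpGs are indexed by the
# forward-strand position of the C; a 4-CpG segment spans from the first
# C to one past the last G (last position + 2), so the span includes the
# full dinucleotides.

#' Parse a read-pattern table
#'
#' Reads the tab-delimited read-pattern dialect: one row per read (bulk
#' mode) or per cell-read (single-cell mode) with columns
#' `unit_id`, `chrom`, comma-separated ascending CpG positions, and a call
#' string over `{0,1}` (1 = methylated) of the same length. Lines starting
#' with `#` are comments. Plain or gzip-compressed files are accepted.
#'
#' @param path path to the table.
#' @return a `read_calls` object: a `data.table` with columns `unit_id`,
#'   `chrom`, and list-columns `pos` (integer positions) and `calls`
#'   (integer 0/1 states).
#' @export
parse_read_patterns <- function(path) {
  if (!file.exists(path)) stop("read-pattern file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(read_calls())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    stop("line ", lineno[which(nf != 4L)[1]], ": expected 4 tab-separated fields")
  }
  unit_id <- vapply(parts, `[`, "", 1L)
  chrom <- vapply(parts, `[`, "", 2L)
  pos <- lapply(strsplit(vapply(parts, `[`, "", 3L), ",", fixed = TRUE),
                function(p) suppressWarnings(as.integer(p)))
  callstr <- vapply(parts, `[`, "", 4L)
  bad_pos <- vapply(pos, function(p) anyNA(p), TRUE)
  if (any(bad_pos)) {
    stop("line ", lineno[which(bad_pos)[1]], ": non-integer CpG position")
  }
  unsorted <- vapply(pos, function(p) length(p) > 1L && any(diff(p) <= 0L), TRUE)
  if (any(unsorted)) {
    stop("line ", lineno[which(unsorted)[1]], ": positions not ascending")
  }
  nonbin <- grepl("[^01]", callstr)
  if (any(nonbin)) {
    stop("line ", lineno[which(nonbin)[1]], ": non-binary call characters")
  }
  len_mismatch <- nchar(callstr) != lengths(pos)
  if (any(len_mismatch)) {
    stop("line ", lineno[which(len_mismatch)[1]],
         ": call string length differs from number of positions")
  }
  calls <- lapply(strsplit(callstr, "", fixed = TRUE), as.integer)
  read_calls(unit_id, chrom, pos, calls)
}

#' Construct a read_calls object
#'
#' @param unit_id character; read id (bulk) or cell id (single-cell).
#' @param chrom character chromosome names.
#' @param pos list of strictly increasing integer CpG positions (0-based).
#' @param calls list of 0/1 integer vectors, same lengths as `pos`.
#' @return a `read_calls` data.table.
#' @export
read_calls <- function(unit_id = character(), chrom = character(),
                       pos = list(), calls = list()) {
  dt <- data.table(unit_id = unit_id, chrom = chrom, pos = pos, calls = calls)
  if (nrow(dt)) {
    stopifnot(all(lengths(dt$pos) == lengths(dt$calls)),
              all(lengths(dt$pos) >= 1L))
  }
  data.table::setattr(dt, "class", c("read_calls", class(dt)))
  dt
}

#' Write a read-pattern table
#'
#' @param reads a `read_calls` object.
#' @param path output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_read_patterns <- function(reads, path) {
  lines <- sprintf("%s\t%s\t%s\t%s",
                   reads$unit_id, reads$chrom,
                   vapply(reads$pos, paste, "", collapse = ","),
                   vapply(reads$calls, paste, "", collapse = ""))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Extract 4-CpG segments from reads
#'
#' Every sliding window of four consecutive called CpGs within one read
#' yields one pattern observation (a read with c >= 4 called CpGs yields
#' c - 3 windows); observations sharing a segment key (chromosome plus the
#' four positions) are aggregated. "Consecutive" means consecutive among
#' the CpGs called in that read: uncalled intervening CpGs break adjacency
#' because patterns are read-derived, not genome-derived.
#'
#' In single-cell mode, multiple reads of one cell over the same segment
#' are reduced to a single per-cell observation by per-site majority; a
#' tied site is dropped and the pattern is kept only when all four sites
#' resolve.
#'
#' @param reads a `read_calls` object.
#' @param mode `"bulk"` (units are reads) or `"single_cell"` (units are
#'   cells).
#' @return a `segment_profiles` object: a `data.table` with columns
#'   `chrom`, `p1`..`p4`, `unit_id`, `pattern`, one row per observation,
#'   with the mode stored as an attribute.
#' @export
extract_segments <- function(reads, mode = c("bulk", "single_cell")) {
  mode <- match.arg(mode)
  empty <- data.table(chrom = character(), p1 = integer(), p2 = integer(),
                      p3 = integer(), p4 = integer(), unit_id = character(),
                      pattern = character())
  if (nrow(reads) == 0L) return(segment_profiles(empty, mode))
  n <- lengths(reads$pos)
  nw <- pmax(n - 3L, 0L)
  if (sum(nw) == 0L) return(segment_profiles(empty, mode))
  posv <- unlist(reads$pos, use.names = FALSE)
  callv <- unlist(reads$calls, use.names = FALSE)
  off <- cumsum(c(0L, n))[seq_along(n)]         # per-read offset into posv
  ridx <- rep.int(seq_along(n), nw)             # read index per window
  wstart <- off[ridx] + sequence(nw)            # global index of window start
  dt <- data.table(
    chrom = reads$chrom[ridx],
    p1 = posv[wstart], p2 = posv[wstart + 1L],
    p3 = posv[wstart + 2L], p4 = posv[wstart + 3L],
    unit_id = reads$unit_id[ridx],
    m1 = callv[wstart], m2 = callv[wstart + 1L],
    m3 = callv[wstart + 2L], m4 = callv[wstart + 3L]
  )
  if (mode == "bulk") {
    # a read contributes at most one pattern per segment
    dt <- unique(dt, by = c("chrom", "p1", "p2", "p3", "p4", "unit_id"))
  } else {
    # per-cell majority at each site; ties drop the site (and the pattern)
    dt <- dt[, {
      nr <- .N
      ms <- c(sum(m1), sum(m2), sum(m3), sum(m4))
      maj <- ifelse(2L * ms > nr, 1L, ifelse(2L * ms < nr, 0L, NA_integer_))
      list(m1 = maj[1], m2 = maj[2], m3 = maj[3], m4 = maj[4])
    }, by = c("chrom", "p1", "p2", "p3", "p4", "unit_id")]
    dt <- dt[complete.cases(dt)]
  }
  dt[, pattern := paste0(m1, m2, m3, m4)]
  dt[, c("m1", "m2", "m3", "m4") := NULL]
  setorder(dt, chrom, p1, p2, p3, p4, unit_id)
  segment_profiles(dt, mode)
}

segment_profiles <- function(dt, mode) {
  data.table::setattr(dt, "mode", mode)
  if (!inherits(dt, "segment_profiles")) {
    data.table::setattr(dt, "class", c("segment_profiles", class(dt)))
  }
  dt
}

#' Filter segment profiles
#'
#' Retains segments with coverage (number of unit observations) at least
#' `min_cov`, optionally restricted to autosomes, and with no positional
#' overlap with blacklist intervals (e.g. known imprinted regions, where
#' allele-specific methylation mimics cell-type bipolarity).
#'
#' @param profiles a `segment_profiles` object.
#' @param blacklist a `GRanges` of intervals to exclude, a path to a BED
#'   file, or `NULL` for an explicitly empty blacklist.
#' @param min_cov minimum number of distinct units covering the segment.
#' @param autosomes_only drop segments on sex/mitochondrial chromosomes.
#' @return the filtered `segment_profiles`.
#' @export
filter_segments <- function(profiles, blacklist = NULL, min_cov = 10L,
                            autosomes_only = TRUE) {
  mode <- attr(profiles, "mode")
  dt <- as.data.table(profiles)
  if (is.character(blacklist)) blacklist <- read_bed(blacklist)
  if (nrow(dt)) {
    if (autosomes_only) dt <- dt[is_autosome(chrom)]
    dt[, .cov := .N, by = c("chrom", "p1", "p2", "p3", "p4")]
    dt <- dt[.cov >= min_cov][, .cov := NULL]
    if (!is.null(blacklist) && length(blacklist) && nrow(dt)) {
      gr <- GenomicRanges::GRanges(
        dt$chrom, IRanges::IRanges(start = dt$p1 + 1L, end = dt$p4 + 2L))
      # disjoint seqlevels (e.g. blacklist chromosomes absent from the
      # data) are legitimate here
      hit <- suppressWarnings(IRanges::overlapsAny(gr, blacklist))
      dt <- dt[!hit]
    }
  }
  segment_profiles(dt, mode)
}

#' Merge segments into non-overlapping loci
#'
#' Standard interval merge of segment spans `[p1, p4 + 2)`. Overlapping
#' spans are always merged; bookended (abutting) spans are merged when
#' `merge_bookended = TRUE`.
#'
#' @param segments a `segment_profiles` object or a `data.table` with
#'   columns `chrom`, `p1`..`p4` (one row per segment key is sufficient).
#' @param merge_bookended merge intervals that touch end-to-start.
#' @return a `data.table` of loci: `chrom`, `start`, `end` (0-based
#'   half-open), `n_source_segments`, sorted and pairwise non-overlapping
#'   per chromosome.
#' @export
merge_to_loci <- function(segments, merge_bookended = TRUE) {
  keys <- unique(as.data.table(segments)[, c("chrom", "p1", "p4")])
  if (nrow(keys) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_source_segments = integer()))
  }
  gr <- GenomicRanges::GRanges(
    keys$chrom, IRanges::IRanges(start = keys$p1 + 1L, end = keys$p4 + 2L))
  red <- GenomicRanges::reduce(
    gr, min.gapwidth = if (merge_bookended) 1L else 0L, with.revmap = TRUE)
  out <- data.table(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_source_segments = lengths(S4Vectors::mcols(red)$revmap)
  )
  setorder(out, chrom, start)
  out
}

#' Read / write BED intervals
#'
#' Minimal BED3+ support (chrom, start, end, further columns ignored on
#' read); coordinates are kept 0-based half-open externally and converted
#' to the 1-based closed convention of `GRanges` internally.
#'
#' @param path BED file path.
#' @return `read_bed()` returns a `GRanges`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  dt <- tryCatch(fread(path, header = FALSE, sep = "\t"),
                 error = function(e) stop("failed to read BED: ", conditionMessage(e)))
  if (nrow(dt) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(as.character(dt[[1]]),
                         IRanges::IRanges(start = dt[[2]] + 1L, end = dt[[3]]))
}

#' @rdname read_bed
#' @param loci a loci `data.table` (from [merge_to_loci()]) or a `GRanges`.
#' @export
write_bed <- function(loci, path) {
  if (inherits(loci, "GRanges")) {
    dt <- data.table(chrom = as.character(GenomicRanges::seqnames(loci)),
                     start = GenomicRanges::start(loci) - 1L,
                     end = GenomicRanges::end(loci))
  } else {
    dt <- as.data.table(loci)
  }
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write a methylation matrix
#'
#' Matrix dialect: tab-separated with a header; first column `locus`
#' holds `"chrom:start-end"` identifiers, remaining columns one sample
#' each with levels in `[0, 1]`; missing values written as `NA`.
#'
#' @param path file path.
#' @return `read_meth_matrix()` returns a numeric matrix with locus row
#'   names and sample column names.
#' @export
read_meth_matrix <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_meth_matrix
#' @param m numeric matrix, loci in rows (named), samples in columns.
#' @export
write_meth_matrix <- function(m, path) {
  dt <- data.table(locus = rownames(m))
  dt <- cbind(dt, as.data.table(m))
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# segment spans as GRanges (1-based closed internally)
segments_granges <- function(dt) {
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(start = dt$p1 + 1L, end = dt$p4 + 2L))
}
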